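Activated_B_cell	synthetic stand-in immune signature	IMM001	IMM002	IMM003	IMM004	IMM005	IMM006	IMM007	IMM008	IMM009	IMM010
Activated_CD4_T_cell	synthetic stand-in immune signature	IMM011	IMM012	IMM013	IMM014	IMM015	IMM016	IMM017	IMM018	IMM019	IMM020
Activated_CD8_T_cell	synthetic stand-in immune signature	IMM021	IMM022	IMM023	IMM024	IMM025	IMM026	IMM027	IMM028	IMM029	IMM030
Activated_dendritic_cell	synthetic stand-in immune signature	IMM031	IMM032	IMM033	IMM034	IMM035	IMM036	IMM037	IMM038	IMM039	IMM040
CD56bright_NK_cell	synthetic stand-in immune signature	IMM041	IMM042	IMM043	IMM044	IMM045	IMM046	IMM047	IMM048	IMM049	IMM050
CD56dim_NK_cell	synthetic stand-in immune signature	IMM051	IMM052	IMM053	IMM054	IMM055	IMM056	IMM057	IMM058	IMM059	IMM060
Central_memory_CD4_T_cell	synthetic stand-in immune signature	IMM061	IMM062	IMM063	IMM064	IMM065	IMM066	IMM067	IMM068	IMM069	IMM070
Central_memory_CD8_T_cell	synthetic stand-in immune signature	IMM071	IMM072	IMM073	IMM074	IMM075	IMM076	IMM077	IMM078	IMM079	IMM080
Effector_memory_CD4_T_cell	synthetic stand-in immune signature	IMM081	IMM082	IMM083	IMM084	IMM085	IMM086	IMM087	IMM088	IMM089	IMM090
Effector_memory_CD8_T_cell	synthetic stand-in immune signature	IMM091	IMM092	IMM093	IMM094	IMM095	IMM096	IMM097	IMM098	IMM099	IMM100
Eosinophil	synthetic stand-in immune signature	IMM101	IMM102	IMM103	IMM104	IMM105	IMM106	IMM107	IMM108	IMM109	IMM110
Gamma_delta_T_cell	synthetic stand-in immune signature	IMM111	IMM112	IMM113	IMM114	IMM115	IMM116	IMM117	IMM118	IMM119	IMM120
Immature_B_cell	synthetic stand-in immune signature	IMM121	IMM122	IMM123	IMM124	IMM125	IMM126	IMM127	IMM128	IMM129	IMM130
Immature_dendritic_cell	synthetic stand-in immune signature	IMM131	IMM132	IMM133	IMM134	IMM135	IMM136	IMM137	IMM138	IMM139	IMM140
MDSC	synthetic stand-in immune signature	IMM141	IMM142	IMM143	IMM144	IMM145	IMM146	IMM147	IMM148	IMM149	IMM150
Macrophage	synthetic stand-in immune signature	IMM151	IMM152	IMM153	IMM154	IMM155	IMM156	IMM157	IMM158	IMM159	IMM160
Mast_cell	synthetic stand-in immune signature	IMM161	IMM162	IMM163	IMM164	IMM165	IMM166	IMM167	IMM168	IMM169	IMM170
Memory_B_cell	synthetic stand-in immune signature	IMM171	IMM172	IMM173	IMM174	IMM175	IMM176	IMM177	IMM178	IMM179	IMM180
Monocyte	synthetic stand-in immune signature	IMM181	IMM182	IMM183	IMM184	IMM185	IMM186	IMM187	IMM188	IMM189	IMM190
Natural_killer_T_cell	synthetic stand-in immune signature	IMM191	IMM192	IMM193	IMM194	IMM195	IMM196	IMM197	IMM198	IMM199	IMM200
Natural_killer_cell	synthetic stand-in immune signature	IMM201	IMM202	IMM203	IMM204	IMM205	IMM206	IMM207	IMM208	IMM209	IMM210
Neutrophil	synthetic stand-in immune signature	IMM211	IMM212	IMM213	IMM214	IMM215	IMM216	IMM217	IMM218	IMM219	IMM220
Plasmacytoid_dendritic_cell	synthetic stand-in immune signature	IMM221	IMM222	IMM223	IMM224	IMM225	IMM226	IMM227	IMM228	IMM229	IMM230
Regulatory_T_cell	synthetic stand-in immune signature	IMM231	IMM232	IMM233	IMM234	IMM235	IMM236	IMM237	IMM238	IMM239	IMM240
T_follicular_helper_cell	synthetic stand-in immune signature	IMM241	IMM242	IMM243	IMM244	IMM245	IMM246	IMM247	IMM248	IMM249	IMM250
Type_1_T_helper_cell	synthetic stand-in immune signature	IMM251	IMM252	IMM253	IMM254	IMM255	IMM256	IMM257	IMM258	IMM259	IMM260
Type_17_T_helper_cell	synthetic stand-in immune signature	IMM261	IMM262	IMM263	IMM264	IMM265	IMM266	IMM267	IMM268	IMM269	IMM270
Type_2_T_helper_cell	synthetic stand-in immune signature	IMM271	IMM272	IMM273	IMM274	IMM275	IMM276	IMM277	IMM278	IMM279	IMM280
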