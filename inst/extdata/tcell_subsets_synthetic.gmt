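T_follicular_helper	synthetic stand-in T-cell subset gene list	TCG001	TCG002	TCG003	TCG004	TCG005	TCG006	TCG007	TCG008	TCG009	TCG010	TCG011	TCG012	TCG013	TCG014	TCG015	TCG016	TCG017	TCG018	TCG019	TCG020	TCG021	TCG022	TCG023	TCG024	TCG025	TCG026	TCG027	TCG028	TCG029	TCG030	TCG031	TCG032	TCG033	TCG034	TCG035	TCG036
Type_1_T_helper	synthetic stand-in T-cell subset gene list	TCG037	TCG038	TCG039	TCG040	TCG041	TCG042	TCG043	TCG044	TCG045	TCG046	TCG047	TCG048	TCG049	TCG050	TCG051	TCG052	TCG053	TCG054	TCG055	TCG056	TCG057	TCG058	TCG059	TCG060	TCG061	TCG062	TCG063	TCG064	TCG065	TCG066	TCG067	TCG068	TCG069	TCG070	TCG071	TCG072	TCG073	TCG074	TCG075	TCG076	TCG077	TCG078	TCG079	TCG080	TCG081	TCG082	TCG083	TCG084	TCG085	TCG086	TCG087	TCG088	TCG089	TCG090	TCG091	TCG092	TCG093	TCG094	TCG095	TCG096	TCG097	TCG098	TCG099	TCG100	TCG101	TCG102	TCG103	TCG104	TCG105	TCG106	TCG107	TCG108	TCG109	TCG110	TCG111	TCG112	TCG113
Type_17_T_helper	synthetic stand-in T-cell subset gene list	TCG114	TCG115	TCG116	TCG117	TCG118	TCG119	TCG120	TCG121	TCG122	TCG123	TCG124	TCG125	TCG126	TCG127	TCG128	TCG129	TCG130	TCG131	TCG132	TCG133	TCG134	TCG135	TCG136	TCG137	TCG138	TCG139	TCG140
Type_2_T_helper	synthetic stand-in T-cell subset gene list	TCG141	TCG142	TCG143	TCG144	TCG145	TCG146	TCG147	TCG148	TCG149	TCG150	TCG151	TCG152	TCG153	TCG154	TCG155	TCG156	TCG157	TCG158	TCG159	TCG160	TCG161	TCG162	TCG163	TCG164	TCG165	TCG166	TCG167	TCG168	TCG169
Regulatory_T_cell	synthetic stand-in T-cell subset gene list	TCG170	TCG171	TCG172	TCG173	TCG174	TCG175	TCG176	TCG177	TCG178	TCG179	TCG180	TCG181	TCG182	TCG183	TCG184	TCG185	TCG186	TCG187	TCG188	TCG189
Natural_killer_T	synthetic stand-in T-cell subset gene list	TCG190	TCG191	TCG192	TCG193	TCG194	TCG195	TCG196	TCG197	TCG198	TCG199	TCG200	TCG201	TCG202	TCG203	TCG204	TCG205	TCG206	TCG207	TCG208	TCG209	TCG210	TCG211	TCG212	TCG213	TCG214	TCG215	TCG216	TCG217	TCG218	TCG219	TCG220	TCG221	TCG222	TCG223	TCG224	TCG225	TCG226	TCG227	TCG228	TCG229	TCG230	TCG231	TCG232	TCG233	TCG001	TCG002	TCG003	TCG004	TCG005	TCG006	TCG007	TCG008	TCG009	TCG010	TCG011	TCG012	TCG013	TCG014	TCG015	TCG016	TCG017	TCG018	TCG019	TCG020
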