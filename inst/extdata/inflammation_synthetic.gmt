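chemokine	synthetic stand-in inflammation list	INF001	INF002	INF003	INF004	INF005	INF006	INF007	INF008	INF009	INF010	INF011	INF012	INF013	INF014	INF015
cytokine	synthetic stand-in inflammation list	INF010	INF011	INF012	INF013	INF014	INF015	INF016	INF017	INF018	INF019	INF020	INF021	INF022	INF023	INF024	INF025	INF026	INF027	INF028	INF029	INF030
inflammatory_response	synthetic stand-in inflammation list	INF025	INF026	INF027	INF028	INF029	INF030	INF031	INF032	INF033	INF034	INF035	INF036	INF037	INF038	INF039	INF040	INF041	INF042	INF043	INF044	INF045	INF046	INF047	INF048	INF049	INF050
interferon_response	synthetic stand-in inflammation list	INF045	INF046	INF047	INF048	INF049	INF050	INF051	INF052	INF053	INF054	INF055	INF056	INF057	INF058	INF059	INF060
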