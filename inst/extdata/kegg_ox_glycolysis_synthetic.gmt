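OX_synthetic	synthetic stand-in for the KEGG 00190 oxidative phosphorylation set (116 members)	OXsyn001	OXsyn002	OXsyn003	OXsyn004	OXsyn005	OXsyn006	OXsyn007	OXsyn008	OXsyn009	OXsyn010	OXsyn011	OXsyn012	OXsyn013	OXsyn014	OXsyn015	OXsyn016	OXsyn017	OXsyn018	OXsyn019	OXsyn020	OXsyn021	OXsyn022	OXsyn023	OXsyn024	OXsyn025	OXsyn026	OXsyn027	OXsyn028	OXsyn029	OXsyn030	OXsyn031	OXsyn032	OXsyn033	OXsyn034	OXsyn035	OXsyn036	OXsyn037	OXsyn038	OXsyn039	OXsyn040	OXsyn041	OXsyn042	OXsyn043	OXsyn044	OXsyn045	OXsyn046	OXsyn047	OXsyn048	OXsyn049	OXsyn050	OXsyn051	OXsyn052	OXsyn053	OXsyn054	OXsyn055	OXsyn056	OXsyn057	OXsyn058	OXsyn059	OXsyn060	OXsyn061	OXsyn062	OXsyn063	OXsyn064	OXsyn065	OXsyn066	OXsyn067	OXsyn068	OXsyn069	OXsyn070	OXsyn071	OXsyn072	OXsyn073	OXsyn074	OXsyn075	OXsyn076	OXsyn077	OXsyn078	OXsyn079	OXsyn080	OXsyn081	OXsyn082	OXsyn083	OXsyn084	OXsyn085	OXsyn086	OXsyn087	OXsyn088	OXsyn089	OXsyn090	OXsyn091	OXsyn092	OXsyn093	OXsyn094	OXsyn095	OXsyn096	OXsyn097	OXsyn098	OXsyn099	OXsyn100	OXsyn101	OXsyn102	OXsyn103	OXsyn104	OXsyn105	OXsyn106	OXsyn107	OXsyn108	OXsyn109	OXsyn110	OXsyn111	OXsyn112	OXsyn113	OXsyn114	OXsyn115	OXsyn116
glycolysis_synthetic	synthetic stand-in for the KEGG 00010 glycolysis set (60 members)	GLYsyn01	GLYsyn02	GLYsyn03	GLYsyn04	GLYsyn05	GLYsyn06	GLYsyn07	GLYsyn08	GLYsyn09	GLYsyn10	GLYsyn11	GLYsyn12	GLYsyn13	GLYsyn14	GLYsyn15	GLYsyn16	GLYsyn17	GLYsyn18	GLYsyn19	GLYsyn20	GLYsyn21	GLYsyn22	GLYsyn23	GLYsyn24	GLYsyn25	GLYsyn26	GLYsyn27	GLYsyn28	GLYsyn29	GLYsyn30	GLYsyn31	GLYsyn32	GLYsyn33	GLYsyn34	GLYsyn35	GLYsyn36	GLYsyn37	GLYsyn38	GLYsyn39	GLYsyn40	GLYsyn41	GLYsyn42	GLYsyn43	GLYsyn44	GLYsyn45	GLYsyn46	GLYsyn47	GLYsyn48	GLYsyn49	GLYsyn50	GLYsyn51	GLYsyn52	GLYsyn53	GLYsyn54	GLYsyn55	GLYsyn56	GLYsyn57	GLYsyn58	GLYsyn59	GLYsyn60
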