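cellular_response_to_bacterium_01	planted synthetic category	NM_000018	NM_000003	NM_000006	NM_000016	NM_000001	NM_000011	NM_000007	NM_000005	NM_000020
cellular_response_to_microbial_stimulus_02	planted synthetic category	NM_000017	NM_000007	NM_000016	NM_000010	NM_000019	NM_000008	NM_000001	NM_000009	NM_000020	NM_000002
cellular_response_to_bacterium_03	planted synthetic category	NM_000007	NM_000015	NM_000014	NM_000019	NM_000013	NM_000020	NM_000009	NM_000012	NM_000017	NM_000005	NM_000010	NM_000008	NM_000002	NM_000016	NM_000018	NM_000011
cellular_response_to_microbial_stimulus_04	planted synthetic category	NM_000004	NM_000018	NM_000003	NM_000013	NM_000015	NM_000012	NM_000006
lipid_metabolic_process_01	planted synthetic category	NM_000111	NM_000049	NM_000114	NM_000062	NM_000061	NM_000093	NM_000080	NM_000091	NM_000085	NM_000076	NM_000058	NM_000095	NM_000106	NM_000072	NM_000068	NM_000113	NM_000059	NM_000051	NM_000074	NM_000066	NM_000083	NM_000067	NM_000064	NM_000034	NM_000032	NM_000031	NM_000042	NM_000069	NM_000048	NM_000084	NM_000041	NM_000105	NM_000052	NM_000033	NM_000040	NM_000050	NM_000097	NM_000047	NM_000086	NM_000079	NM_000081	NM_000104	NM_000092	NM_000075	NM_000056	NM_000053	NM_000082	NM_000055	NM_000036	NM_000109	NM_000073	NM_000110	NM_000099	NM_000096	NM_000071	NM_000108	NM_000078	NM_000046	NM_000057	NM_000094
neuron_differentiation_02	planted synthetic category	NM_000074	NM_000046	NM_000098	NM_000081	NM_000102	NM_000052	NM_000059	NM_000036	NM_000112	NM_000097	NM_000032	NM_000047	NM_000057	NM_000056	NM_000094	NM_000101	NM_000049	NM_000107	NM_000095	NM_000043	NM_000079	NM_000080	NM_000096	NM_000050	NM_000093	NM_000067	NM_000039	NM_000060	NM_000091	NM_000113	NM_000064	NM_000061	NM_000105	NM_000069	NM_000045	NM_000034	NM_000110	NM_000072	NM_000100	NM_000099	NM_000068	NM_000048	NM_000066	NM_000063	NM_000114	NM_000077	NM_000109	NM_000083	NM_000111	NM_000087	NM_000073	NM_000031	NM_000082	NM_000088	NM_000065	NM_000044	NM_000037	NM_000035	NM_000058	NM_000084
cilium_assembly_03	planted synthetic category	NM_000097	NM_000060	NM_000109	NM_000075	NM_000110	NM_000055	NM_000099	NM_000091	NM_000100	NM_000033	NM_000084	NM_000031	NM_000086	NM_000113	NM_000042	NM_000087	NM_000036	NM_000111	NM_000094	NM_000038	NM_000090	NM_000070	NM_000049	NM_000037	NM_000085	NM_000076	NM_000106	NM_000101	NM_000114	NM_000045	NM_000063	NM_000092	NM_000074	NM_000057	NM_000050	NM_000035	NM_000059	NM_000080	NM_000048	NM_000103	NM_000093	NM_000043	NM_000053	NM_000064	NM_000105	NM_000077	NM_000054	NM_000058	NM_000039	NM_000072	NM_000102	NM_000071	NM_000073	NM_000107	NM_000051	NM_000044	NM_000088	NM_000096	NM_000041	NM_000078
dna_repair_04	planted synthetic category	NM_000055	NM_000109	NM_000100	NM_000114	NM_000087	NM_000073	NM_000038	NM_000077	NM_000063	NM_000105	NM_000091	NM_000098	NM_000075	NM_000102	NM_000035	NM_000076	NM_000097	NM_000045	NM_000034	NM_000088	NM_000103	NM_000062	NM_000071	NM_000051	NM_000054	NM_000056	NM_000046	NM_000082	NM_000036	NM_000065	NM_000032	NM_000110	NM_000086	NM_000089	NM_000059	NM_000112	NM_000095	NM_000037	NM_000047	NM_000107	NM_000072	NM_000113	NM_000060	NM_000067	NM_000033	NM_000111	NM_000070	NM_000099	NM_000094	NM_000050	NM_000064	NM_000106	NM_000042	NM_000069	NM_000096	NM_000066	NM_000049	NM_000044	NM_000040	NM_000031
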