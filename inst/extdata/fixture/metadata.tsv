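sample_id	group	labeling_batch	array_batch
S001	RUS	L1	A1
S002	RUS	L2	A2
S003	RUS	L1	A3
S004	RUS	L2	A1
S005	RUS	L1	A2
S006	RUS	L2	A3
S007	RUS	L1	A1
S008	RUS	L2	A2
S009	RUS	L1	A3
S010	RUS	L2	A1
S011	RUS	L1	A2
S012	RUS	L2	A3
S013	RUS	L1	A1
S014	RUS	L2	A2
S015	RUS	L1	A3
S016	RUS	L2	A1
S017	RUS	L1	A2
S018	RUS	L2	A3
S019	RUS	L1	A1
S020	RUS	L2	A2
S021	RUS	L1	A3
S022	FIN	L1	A1
S023	FIN	L2	A2
S024	FIN	L1	A3
S025	FIN	L2	A1
S026	FIN	L1	A2
S027	FIN	L2	A3
S028	FIN	L1	A1
S029	FIN	L2	A2
S030	FIN	L1	A3
S031	FIN	L2	A1
S032	FIN	L1	A2
S033	FIN	L2	A3
S034	FIN	L1	A1
S035	FIN	L2	A2
S036	FIN	L1	A3
S037	FIN	L2	A1
S038	FIN	L1	A2
S039	FIN	L2	A3
S040	FIN	L1	A1
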