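gene1	gene2	confidence
G0001	G0002	999
G0001	G0003	999
G0002	G0003	999
G0001	G0004	999
G0002	G0004	999
G0003	G0004	999
G0004	G0005	999
G0001	G0005	999
G0003	G0005	999
G0004	G0006	999
G0002	G0006	999
G0003	G0006	999
G0003	G0007	999
G0002	G0007	999
G0006	G0007	999
G0001	G0008	999
G0007	G0008	999
G0006	G0008	999
G0006	G0009	999
G0004	G0009	999
G0003	G0009	999
G0007	G0010	999
G0001	G0010	999
G0008	G0010	999
G0002	G0011	999
G0004	G0011	999
G0001	G0011	999
G0001	G0012	999
G0007	G0012	999
G0010	G0012	999
G0009	G0013	999
G0003	G0013	999
G0007	G0013	999
G0010	G0014	999
G0001	G0014	999
G0002	G0014	999
G0005	G0015	999
G0003	G0015	999
G0002	G0015	999
G0015	G0016	999
G0008	G0016	999
G0009	G0016	999
G0001	G0017	999
G0016	G0017	999
G0002	G0017	999
G0009	G0018	999
G0015	G0018	999
G0016	G0018	999
G0009	G0019	999
G0005	G0019	999
G0015	G0019	999
G0007	G0020	999
G0006	G0020	999
G0003	G0020	999
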