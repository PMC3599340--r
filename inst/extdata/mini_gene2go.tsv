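g0001	GO:1000003
g0001	GO:2000003
g0002	GO:1000003
g0002	GO:2000002
g0003	GO:1000004
g0003	GO:2000001
g0004	GO:1000004
g0005	GO:1000002
g0005	GO:2000003
g0006	GO:1000002
g0007	GO:1000001
g0007	GO:2000001
g0008	GO:1000001
g0009	GO:1000003
g0010	GO:1000002
g0010	GO:2000002
g0011	GO:1000004
g0012	GO:1000001
g0013	GO:2000001
g0014	GO:1000002
g0015	GO:2000003
g0016	GO:1000003
g0017	GO:1000001
g0018	GO:2000002
g0019	GO:1000002
g0020	GO:2000001
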