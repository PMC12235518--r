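gene	planted_log2FC	rewired	deg
G0001	0.189856805766	FALSE	FALSE
G0002	-0.242065503688	FALSE	FALSE
G0003	-0.112462442187	FALSE	FALSE
G0004	-0.3	TRUE	FALSE
G0005	-0.106230607931	FALSE	FALSE
G0006	0.176840498997	FALSE	FALSE
G0007	-0.0764624748358	FALSE	FALSE
G0008	-0.0205307607172	FALSE	FALSE
G0009	0.3	TRUE	FALSE
G0010	-0.201592950835	FALSE	FALSE
G0011	0.115286632064	FALSE	FALSE
G0012	-0.6	FALSE	TRUE
G0013	0.209841408129	FALSE	FALSE
G0014	-0.6	FALSE	TRUE
G0015	-0.247978269198	FALSE	FALSE
G0016	0.163128333577	FALSE	FALSE
G0017	-0.0420125431322	FALSE	FALSE
G0018	0.6	FALSE	TRUE
G0019	0.064729660772	FALSE	FALSE
G0020	0.6	FALSE	TRUE
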