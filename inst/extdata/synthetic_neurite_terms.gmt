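growth of neurites	synthetic example term	SIM00001	SIM00002	SIM00003	SIM00004	SIM00005	SIM00006
regeneration of neurites	synthetic example term	SIM00002	SIM00003	SIM00007	SIM00008
synaptic transmission	synthetic example term	SIM00001	SIM00004	SIM00009	SIM00010	SIM00011
dendritic branching	synthetic example term	SIM00005	SIM00006	SIM00012
oxidative phosphorylation	synthetic example term	SIM00013	SIM00014	SIM00015	SIM00016
axon guidance	synthetic example term	SIM00007	SIM00010	SIM00017	SIM00018
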