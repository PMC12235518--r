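sample	condition
c1_s001	c1
c1_s002	c1
c1_s003	c1
c1_s004	c1
c1_s005	c1
c1_s006	c1
c1_s007	c1
c1_s008	c1
c1_s009	c1
c1_s010	c1
c1_s011	c1
c1_s012	c1
c1_s013	c1
c1_s014	c1
c1_s015	c1
c2_s001	c2
c2_s002	c2
c2_s003	c2
c2_s004	c2
c2_s005	c2
c2_s006	c2
c2_s007	c2
c2_s008	c2
c2_s009	c2
c2_s010	c2
c2_s011	c2
c2_s012	c2
c2_s013	c2
c2_s014	c2
c2_s015	c2
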