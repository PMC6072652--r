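sp1	sp10
sp1	sp12
sp1	sp7
sp10	sp11
sp10	sp6
sp10	sp8
sp10	sp9
sp11	sp10
sp11	sp5
sp11	sp8
sp14	sp13
sp14	sp3
sp15	sp1
sp15	sp13
sp15	sp4
sp15	sp7
sp15	sp8
sp15	sp9
sp2	sp12
sp2	sp3
sp2	sp6
sp3	sp5
sp3	sp6
sp4	sp10
sp4	sp5
sp4	sp6
sp4	sp7
sp5	sp1
sp5	sp7
sp5	sp9
sp6	sp10
sp6	sp11
sp7	sp10
sp8	sp4
sp9	sp8
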