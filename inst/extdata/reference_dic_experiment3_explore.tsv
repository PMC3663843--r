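gam1	gam2	dic_causal	dic_reverse
0.025	0.1	-4415.1	-1563.2
0.025	0.5	-1663.6	-1565.4
0.025	1.0	-5545.9	-1564.4
0.025	3.0	-3414.2	-1564.3
0.025	10.0	-3707.8	-1565.4
0.025	20.0	-5481.7	-1562.4
0.1	0.1	-1884.7	-1567.3
0.1	0.5	-3511.6	-1560.6
0.1	1.0	-1727.2	-1574.4
0.1	3.0	-1944.3	-1565.2
0.1	10.0	-1773.4	-1561.8
0.1	20.0	-1568.8	-1559.1
0.25	0.1	-1569.3	-1564.1
0.25	0.5	-1572.8	-1562.2
0.25	1.0	-1892.8	-1565.1
0.25	3.0	-1565.6	-1562.4
0.25	10.0	-1623.8	-1563.3
0.25	20.0	-1579.4	-1562.3
1	0.1	-1568.4	-1591.7
1	0.5	-1569.5	-1580
1	1.0	-1582.2	-1566.3
1	3.0	-1568.3	-1574.2
1	10.0	-1565.6	-1563.9
1	20.0	-1564.1	-1561.9
10	0.1	-1556.4	-1559.0
10	0.5	-1558.8	-1564.9
10	1.0	-1557.7	-1557.7
10	3.0	-1558.4	-1564.2
10	10.0	-1554.7	-1554.1
10	20.0	-1555.5	-1548.4
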