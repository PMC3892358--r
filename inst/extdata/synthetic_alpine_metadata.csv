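"plot_id","elevation"
"p0001",375
"p0002",447
"p0003",520
"p0004",592
"p0005",665
"p0006",737
"p0007",810
"p0008",882
"p0009",954
"p0010",1027
"p0011",1099
"p0012",1172
"p0013",1244
"p0014",1317
"p0015",1389
"p0016",1462
"p0017",1534
"p0018",1606
"p0019",1679
"p0020",1751
"p0021",1824
"p0022",1896
"p0023",1969
"p0024",2041
"p0025",2113
"p0026",2186
"p0027",2258
"p0028",2331
"p0029",2403
"p0030",2476
"p0031",2548
"p0032",2621
"p0033",2693
"p0034",2765
"p0035",2838
"p0036",2910
"p0037",2983
"p0038",3055
"p0039",3128
"p0040",3200
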