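"plot_id","s001","s002","s003","s004","s005","s006","s007","s008","s009","s010","s011","s012","s013","s014","s015","s016","s017","s018","s019","s020","s021","s022","s023","s024","s025"
"p0001",0,0,0,0,0,0,0,0,0,11.61,0,0,0,0,0,0,28.99,57.46,0,0,0,0,0,1.94,0
"p0002",0,17.92,0.72,0,0,0,0,2.97,0,5.25,0,15.39,0,0,0,0,23.95,7.95,0,0,0,9.46,0,16.4,0
"p0003",8.48,9.54,0,0,4.94,0,0,0,0,0,0,0,3.44,0,1.26,0,22.18,5.3,40.77,0,0,0,0,4.08,0
"p0004",3.57,3.99,0,0,8.77,0,0,0,0,0,0,0,0,0,0,0,42.2,24.03,0,0,0,0,0,17.44,0
"p0005",6.75,0,0,0,0,0,0,0,0,0,0,0,0,0,9.81,0,53.67,6.73,0,0,0,0,0,23.05,0
"p0006",4.82,0,0,0,3.5,0,0,0,0,0,0,0,0,0,58.76,0,11.4,3.44,0,0,0,0,0,18.08,0
"p0007",9.2,0,0,0,0,0,0,0,0,0,0,0,0,0,23.4,0,7.84,5.83,0,0,0,0,0,53.72,0
"p0008",33.97,0,0,0,5.11,0,0,0,0,0,6.63,0,0,0,25.17,0,4.16,16.2,0,0,0,0,0,8.75,0
"p0009",5.56,0,0,0,34.58,0,0,0,0,0,26.09,0,0,0,4.86,0,2.15,22.46,0,0,0,0,0,4.29,0
"p0010",12.92,0,0,2.21,3.73,0,0,0,1.92,0,32.09,0,0,0,6.13,3.62,1.58,28.29,0,0,0,0,0,7.51,0
"p0011",5.6,0,0,2.42,6.78,0,0,0,0,0,27.28,0,0,0,2.43,6.39,3.92,39.84,0,0,0,0,0,5.35,0
"p0012",4.07,0,0,0,9.86,0,0,0,5.18,0,7,0,0,0,1.06,36.54,2.73,3.82,0,0,0,0,0,29.74,0
"p0013",18.1,0,0,1.49,5.86,0,0,0,1.26,46.95,5.07,0,0,0,6.44,0,5.15,4.64,0,0,0,0,0,5.03,0
"p0014",11.63,0,0,53.86,6.2,0,0,0,0,0,11.78,0,0,0,1.67,0,7.81,2.85,0,0,0,0,0,4.21,0
"p0015",2.68,0,0,12.86,43.31,8.35,0,0,4.14,0,0.46,0,0,0,8.9,11.29,8,0,0,0,0,0,0,0,0
"p0016",2.78,0,0,42.69,7.24,9.78,0,0,0,0,5.57,0,0,0,0,5.86,0,0,0,0,26.09,0,0,0,0
"p0017",46.23,0,0,0,28.73,0,0,0,24.08,0,0.96,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"p0018",0,0,0,32.94,0,0,0,0,26.86,26.64,0,0,0,0,13.57,0,0,0,0,0,0,0,0,0,0
"p0019",0,0,10.14,7.99,2.51,2.22,0,0,3.04,19.65,4.64,0,0,0,4.47,8.64,0,0,6.65,0,29.29,0,0,0,0.75
"p0020",7.89,0,0,9.81,0,18.49,0,0,0,6.84,0,0,0,0,0,15.11,0,0,0,0,36.53,0,0,0,5.32
"p0021",0,0,8.67,15.82,0,7.1,0,0,8.02,1.19,0,0,5.53,0,0,1.76,0,0,0,0,3.38,0,0,0,48.54
"p0022",0,0,49.2,0,0,0,0,0,0,0,0,0,6.59,0,0,40.42,0,0,3.79,0,0,0,0,0,0
"p0023",0,35.61,0,0,0,0,1.63,0,0,21.51,0,10.14,3.22,0.95,0,0,0,0,0,19.76,2.49,0,1.11,0,3.58
"p0024",0,31,0,0,0,0,0,0,0,0,0,24.21,0,0,0,0,0,0,0,30.42,0,12.96,0,0,1.41
"p0025",0,4.41,0,0,0,8.09,2.97,0,0,0,0,69.24,1.62,5.34,0,0,0,0,2.21,1.44,0,1.77,2.91,0,0
"p0026",0,0,0,0,0,0,11.23,0,0,0,0,17.77,0,58.15,0,0,0,0,0,0,0,1.07,11.77,0,0
"p0027",0,0,0,0,0,0,29.42,0,0,0,0,0,0,0,0,0,0,0,0,0,0,50.16,20.42,0,0
"p0028",0,0,0,0,0,0,8,19.13,0,0,0,14.1,0,2.94,0,0,0,0,2.95,24.7,0,23.82,4.36,0,0
"p0029",0,2.15,0,0,0,0,30.35,17.31,0,0,0,13.67,0,20.44,0,0,0,0,4.49,0,0,8.88,2.71,0,0
"p0030",0,1.95,5.59,0,0,0,12.28,4.06,0,0,0,9.43,6.7,3.89,0,0,0,0,11.9,27.84,0,4.33,9.33,0,2.7
"p0031",0,6.38,16.55,0,0,0,4.84,16.42,0,0,0,2.74,11.42,0.6,0,0,0,0,15.57,17.08,0,2.43,5.98,0,0
"p0032",0,10.41,3.56,0,0,9.21,3.63,5.17,0,0,0,7.2,24.84,1.65,0,0,0,0,14.97,0.8,0,3.78,8.86,0,5.93
"p0033",0,22.18,0,0,0,0,9.62,6.59,0,0,0,4.67,0,20.56,0,0,0,0,0,8.57,0,8.74,19.06,0,0
"p0034",0,0,0,0,0,0,7.78,3.06,0,0,0,41.11,0,8.96,0,0,0,0,0,4.81,0,18.68,15.59,0,0
"p0035",0,0,0,0,0,0,52.03,10.35,0,0,0,12.78,0,1.88,0,0,0,0,0,1.33,0,18.74,2.89,0,0
"p0036",0,0,0,0,0,0,0,21.09,0,0,0,0,0,16.97,0,0,0,0,0,0,0,40.53,21.41,0,0
"p0037",0,0,14.24,0,3.95,3.2,29.31,1.9,0,3.16,0,9.33,0,3.6,0,0,0,0,6.92,0,0,15.49,2.97,1.22,4.71
"p0038",0,0,0,0,0,0,3.37,51.22,0,0,0,0.43,0,7.86,0,0,0,0,0,0,0,4.8,32.31,0,0
"p0039",0,0,0,0,0,4.68,0,65.06,0,0,0,0,0,30.27,0,0,0,0,0,0,0,0,0,0,0
"p0040",0,0,0,5.75,0,0,0,2.75,0,0,91.49,0,0,0,0,0,0,0,0,0,0,0,0,0,0
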