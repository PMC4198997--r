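date,PM2.5,PM10,CO,NO2,SO2
02-01,135,146,1.99,57,51
02-02,63,93,1.19,30,18
02-03,5,31,0.30,8,4
02-04,26,39,0.62,21,19
02-05,87,101,1.58,48,52
02-06,119,131,2.08,65,67
02-07,94,60,1.45,51,34
02-08,72,43,1.27,38,23
02-09,8,15,0.45,17,15
02-10,23,27,0.74,37,25
02-11,100,114,2.09,78,58
02-12,111,115,2.15,77,53
02-13,190,176,2.85,84,74
02-14,265,295,3.11,94,73
02-15,387,443,3.75,107,102
02-16,296,204,3.18,87,79
02-17,104,50,2.03,71,65
02-18,70,84,1.13,61,37
02-19,66,74,1.23,61,34
02-20,161,171,2.16,78,43
02-21,257,284,2.67,103,77
02-22,262,299,3.32,101,99
02-23,212,248,3.61,92,128
02-24,259,327,4.74,119,133
02-25,353,390,5.29,121,75
02-26,315,250,3.70,105,80
02-27,15,22,0.43,22,12
02-28,77,102,1.50,71,32
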