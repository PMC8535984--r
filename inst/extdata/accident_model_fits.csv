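year,true_value,gm_predicted,gm_relative_error,ggm_predicted,ggm_relative_error
2000,120351,120350.239,-0.000006,120398.833,-0.000037
2001,130491,153846.738,0.151812,130893.063,-0.003072
2002,139393,142948.842,0.024875,137745.544,0.011960
2003,137070,132822.911,-0.031976,139394.868,-0.016678
2004,136755,123414.260,-0.108097,135349.481,0.010384
2005,127089,114672.081,-0.108282,126393.027,0.005506
2006,112879,106549.164,-0.059408,114390.916,-0.013217
2007,101480,99001.642,-0.025034,101753.681,-0.002690
2008,91172,91988.756,0.008879,90729.347,0.004879
2009,83200,85472.636,0.026589,82756.006,0.005365
2010,79552,79418.092,-0.001686,78086.517,0.018767
2011,75572,73792.428,-0.024116,75806.112,-0.003088
2012,71983,68565.264,-0.049846,74231.713,-0.030293
2013,69434,63708.371,-0.089872,71554.045,-0.029629
2014,68061,59195.522,-0.149766,66503.627,0.023418
2015,66182,55002.345,-0.203258,63816.640,0.037065
2016,43062,51106.196,0.157402,44347.675,-0.028991
2017,37852,47486.035,0.202881,39798.570,-0.048911
2018,34046,44122.311,0.228372,32863.764,0.035974
2019,29519,40996.861,0.279969,29087.441,0.014837
2020,27412,38092.805,0.280389,27954.130,-0.019394
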