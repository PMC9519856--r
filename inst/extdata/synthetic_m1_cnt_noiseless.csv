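time,glucose_mean,insulin_mean,aa_mean,glucose_sd,aa_sd
-10,90,8,420,7.2,42
-1,90,8,420,7.2,42
10,123.004732538352,25.0677373576128,487.944055565571,9.84037860306814,48.7944055565571
20,132.729639848857,45.5828889704344,536.032426521001,10.6183711879086,53.6032426521001
30,135,58.4151306837109,567.911820253588,10.8,56.7911820253588
60,126.104996727292,64.8947378037913,600,10.0883997381834,60
90,113.564182247452,55.9702135952422,583.507518508009,9.08513457979617,58.3507518508009
120,104.132688231111,43.9728058341197,551.766406248368,8.33061505848888,55.1766406248368
180,94.5,25.8868675263165,492,7.56,49.2
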