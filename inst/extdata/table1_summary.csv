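system,velocity,n,ln_lr,f_max_mean,f_max_sd,t_max_mean,t_max_sd,d_max_mean,d_max_sd
3EML,0.0001,41,25.32,493.72,38.55,5543.11,751.72,0.47,0.12
3EML,0.0004,41,26.71,514.99,48.76,1484.75,203.58,0.46,0.11
3EML,0.0006,41,27.12,512.40,65.84,1029.35,170.42,0.49,0.12
3EML,0.0008,41,27.40,533.64,44.08,793.23,90.07,0.45,0.10
3EML,0.0010,41,27.63,540.93,59.16,634.05,88.46,0.37,0.06
2YDV,0.0001,41,25.32,505.05,55.78,5050.15,652.31,0.38,0.17
2YDV,0.0004,41,26.71,513.60,60.51,1312.75,174.67,0.34,0.12
2YDV,0.0006,41,27.12,538.82,68.26,1017.53,327.11,0.48,0.17
2YDV,0.0008,41,27.40,526.74,64.54,698.75,101.76,0.37,0.16
2YDV,0.0010,41,27.63,532.02,75.99,601.89,110.70,0.42,0.14
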