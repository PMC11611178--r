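subject,roi_mse_response,roi_mae_lumen_center,huber_loss,mean_ref_diameter,mse,rmse,mad
1,0.00714,4.5126,9.6217,292.7785,205.57,14.3377,4.1147
2,0.01028,6.8277,3.3608,286.2240,17.87,4.2507,1.7039
3,0.00862,5.3201,7.8044,311.1213,109.57,10.4715,4.3095
4,0.01039,6.0514,7.0987,319.3344,82.85,9.1027,3.6739
5,0.00821,10.1607,4.0786,302.1867,58.95,7.7113,1.6738
6,0.01196,5.9619,6.0920,314.1656,74.12,8.6092,3.2429
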