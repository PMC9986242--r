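run_id,pH,incubation_time_h,initial_mb_mgL,glucose_pct,peptone_pct,removal_actual,removal_sd,removal_predicted,snr
L1,5.5,24,10,0.5,1.0,56.68,1.07,56.81,35.07
L2,5.5,36,15,1.0,1.5,61.58,1.09,61.86,35.79
L3,5.5,48,20,1.5,2.0,64.70,1.05,64.94,36.22
L4,5.5,60,25,2.0,2.5,74.14,0.57,73.86,37.40
L5,5.5,72,30,2.5,3.0,71.87,0.53,71.50,37.13
L6,6.5,24,15,1.5,2.5,66.68,0.98,66.31,36.48
L7,6.5,36,20,2.0,3.0,68.47,1.09,68.60,36.71
L8,6.5,48,25,2.5,1.0,75.59,0.83,75.87,37.57
L9,6.5,60,30,0.5,1.5,70.18,0.80,70.43,36.92
L10,6.5,72,10,1.0,2.0,67.70,1.24,67.41,36.61
L11,7.5,24,20,2.5,1.5,72.84,0.90,72.56,37.25
L12,7.5,36,25,0.5,2.0,74.58,0.84,74.21,37.45
L13,7.5,48,30,1.0,2.5,77.20,0.91,77.33,37.75
L14,7.5,60,10,1.5,3.0,75.47,1.11,75.75,37.56
L15,7.5,72,15,2.0,1.0,76.18,0.92,76.43,37.64
L16,8.5,24,25,1.0,3.0,80.25,0.77,80.50,38.09
L17,8.5,36,30,1.5,1.0,83.16,0.86,82.88,38.40
L18,8.5,48,10,2.0,1.5,80.84,0.98,80.47,38.15
L19,8.5,60,15,2.5,2.0,87.14,1.13,87.27,38.80
L20,8.5,72,20,0.5,2.5,81.79,1.11,82.07,38.25
L21,9.5,24,30,2.0,2.0,80.10,0.77,80.38,38.07
L22,9.5,36,10,2.5,2.5,83.40,1.06,83.64,38.42
L23,9.5,48,15,0.5,3.0,79.50,1.06,79.22,38.01
L24,9.5,60,20,1.0,1.0,83.80,0.99,83.43,38.46
L25,9.5,72,25,1.5,1.5,85.80,1.11,85.93,38.67
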