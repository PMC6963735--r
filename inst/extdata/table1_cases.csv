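case,SG,KG,theta_T_amp,dtheta_T,theta_C_amp,dtheta_C,phi,A_mm,U_mm_s,f_hz,St,LT_m,c_m,L_m,nu_m2_s
1,1,1,0.24,0.09,12.90,-3.4,-,25.1,81.5,1.0,0.308,0.26,0.105,0.285,1.0e-6
2,1,2,2.01,0.20,9.03,-2.1,70,22.7,81.5,1.0,0.279,0.26,0.105,0.285,1.0e-6
3,1,3,3.08,0.18,5.48,-1.3,70,23.3,81.5,1.0,0.286,0.26,0.105,0.285,1.0e-6
4,1,4,3.44,0.09,0.18,-0.9,-,22.1,81.5,1.0,0.271,0.26,0.105,0.285,1.0e-6
5,2,1,0.22,-0.07,11.18,-1.5,-,22.1,59.5,1.0,0.371,0.26,0.105,0.285,1.0e-6
6,2,2,2.06,-0.04,9.12,-0.7,70,24.0,59.5,1.0,0.403,0.26,0.105,0.285,1.0e-6
7,2,3,3.04,-0.09,4.91,0.0,70,21.9,59.5,1.0,0.368,0.26,0.105,0.285,1.0e-6
8,2,4,3.63,-0.12,0.68,-1.0,-,22.5,59.5,1.0,0.378,0.26,0.105,0.285,1.0e-6
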