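# Reference breakthrough-indicator panel for lysozyme capture on a
# Tris-functionalized polyacrylonitrile nanofiber membrane bed, as reported
# in a published membrane-chromatography study (one row per operating
# condition; times in min, V_b in mL, MAER in 1e-3 g/mL, capacities in mg/g,
# HMTZ in um, P in mg/(min g)).  W is the adsorptive nanofiber mass per bed
# (0.015 g per layer, support fabric excluded); A = 3.7 cm^2, eps = 0.8367.
Z_um,pH,C0,F,layers,W,t01,t09,HMTZ,Vb,BV,MAER_e3,DBC,EBC,MBU,P
115,5,2.0,1.0,1,0.015,1.86,5.40,75.39,1.86,43.71,8.06,248.01,459.05,54.03,133.33
115,7,2.0,1.0,1,0.015,4.47,6.15,31.42,4.47,105.05,3.36,596.01,733.55,81.25,133.33
115,9,2.0,1.0,1,0.015,4.84,6.43,28.43,4.84,113.75,3.10,645.33,769.65,83.85,133.33
115,9,0.5,1.0,1,0.015,6.80,8.43,22.24,6.80,159.81,2.21,226.67,258.75,87.60,33.33
115,9,1.0,1.0,1,0.015,6.10,8.10,28.39,6.10,143.36,2.46,406.67,473.96,85.80,66.67
115,9,2.0,1.0,1,0.015,4.84,6.43,28.43,4.84,113.75,3.10,645.33,769.65,83.85,133.33
115,9,2.0,0.1,1,0.015,62.87,77.79,22.06,6.29,147.76,2.39,838.27,961.59,87.18,13.33
115,9,2.0,0.5,1,0.015,11.27,14.39,24.93,5.64,132.43,2.66,751.33,875.87,85.78,66.67
115,9,2.0,1.0,1,0.015,4.84,6.43,28.43,4.84,113.75,3.10,645.33,769.65,83.85,133.33
115,9,2.0,1.0,1,0.015,4.84,6.43,28.43,4.84,113.75,3.10,645.33,769.65,83.85,133.33
345,9,2.0,1.0,3,0.045,8.71,12.91,112.24,8.71,68.23,5.17,387.11,469.92,82.38,44.44
575,9,2.0,1.0,5,0.075,12.56,19.73,208.96,12.56,59.04,5.97,334.93,433.79,77.21,26.67
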