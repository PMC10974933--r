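formulation,speed_mm_s,max_pressure_kPa,pressure_flow_cessation_kPa,young_modulus_kPa_mm,shear_stress_steady_kPa,apparent_viscosity,dynamic_viscosity
F1,10,1094.5,900.3,204.1,1759.9,12.8,35.6
F1,20,1435.9,1022.8,303.1,2370.6,7.9,22.9
F1,30,1712.3,1141.0,405.9,2878.5,6.9,11.9
F2,10,511.9,340.9,222.5,901.4,6.3,17.5
F2,20,745.7,385.2,372.9,1237.2,4.3,12.0
F2,30,1033.6,575.2,328.6,1719.6,4.0,11.1
F3,10,678.6,425.0,349.7,1034.7,7.2,20.1
F3,20,814.3,505.3,292.9,1424.8,5.0,13.8
F3,30,1103.9,640.1,286.9,1698.8,3.9,11.0
F4,10,1056.8,757.7,401.7,1835.5,12.8,35.6
F4,20,1445.3,832.7,578.2,2478.5,8.6,24.0
F4,30,1525.2,864.1,462.6,2628.5,6.1,17.0
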