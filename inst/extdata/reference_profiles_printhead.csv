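formulation,speed_mm_s,yield_point_kPa,yield_time_s,max_pressure_kPa,pressure_flow_cessation_kPa,young_modulus_kPa_mm,shear_stress_steady_kPa,apparent_viscosity,dynamic_viscosity
F1,10,471.5,120.0,1402.3,1020.6,240.4,1993.7,13.9,38.6
F1,20,451.5,64.5,1611.2,1160.3,133.2,2248.9,7.8,21.8
F1,30,478.1,40.3,1979.9,1126.2,301.9,2767.7,6.4,18.0
F2,10,450.1,124.4,964.8,631.7,304.9,1473.6,10.2,28.6
F2,20,413.2,40.7,1261.2,744.6,711.4,1831.0,6.4,17.8
F2,30,438.8,35.0,1416.7,748.4,763.1,2243.5,5.2,14.5
F3,10,408.7,162.8,817.9,569.8,166.1,1114.0,7.7,21.6
F3,20,358.3,37.9,1170.6,567.5,178.4,1418.4,4.9,13.7
F3,30,334.8,23.3,1286.5,632.9,682.3,2293.9,5.3,5.5
F4,10,386.4,177.8,1082.3,797.8,170.0,1971.5,13.7,38.2
F4,20,415.0,77.3,2524.7,1647.5,214.6,2722.3,9.5,26.4
F4,30,405.9,44.5,2083.5,1158.9,509.4,3663.3,8.5,23.7
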