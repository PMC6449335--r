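zone	season	u10_m_s	station_distance_km	schema_version
isolated	spring	2.57262749897477	69.0252887597308	1
sporadic	spring	3.43734632148157	27.8963823849335	1
discontinuous	spring	2.77883507536228	66.4560637250543	1
continuous	spring	2.64863129463567	21.8042258452624	1
isolated	summer	4.46298541133137	22.4659122223966	1
sporadic	summer	1.40997425062429	53.5149334045127	1
discontinuous	summer	2.54092980660664	49.0145206614397	1
continuous	summer	1.61761740250138	40.086324994918	1
isolated	autumn	5.76593461191167	31.7730481899343	1
sporadic	autumn	1.44364294609069	30.5055199586786	1
discontinuous	autumn	1.40055862947053	41.8408898334019	1
continuous	autumn	3.47975754617388	67.1336662536487	1
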