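lake_id	zone	latitude	area_m2	depth_m	ice_free_days	season	water_temp_c	air_temp_c	pressure_kpa	pco2_ppmv	pch4_ppmv	doc_mg_l	o2_sat_pct	ch4_dissolved_umol_l	schema_version
L001	isolated	62.2488836260978	44463.658071308	0.744242372987064	170	autumn	3.57362061787589	6.2637666501228	101.46479888016	1397.04264249647	18.29129675774	24.9784638159307	84.9679135316015	0.0422516658140098	1
L001	isolated	62.2488836260978	44463.658071308	0.744242372987064	170	spring	13.0460592846926	14.5861013935749	102.128082817576	400.178511790727	19.2708234845615	15.072279280413	83.892111205521	0.0350015372970498	1
L001	isolated	62.2488836260978	44463.658071308	0.744242372987064	170	summer	10.833417896663	15.6762080885604	100.672432793296	595.705754844893	35.2415446952426	13.3892095956113	95.7998255324116	0.0665584443784096	1
L002	sporadic	63.2622452479787	14240.4059779885	0.456144685783718	165	autumn	0.5	1.54000768605982	101.011154161161	940.092447423506	20.1129509739105	12.1105497148542	113.484819016727	0.0506505839366307	1
L002	sporadic	63.2622452479787	14240.4059779885	0.456144685783718	165	spring	7.84321475236895	7.17125210139895	100.812858899674	859.85617734913	1.80427763123612	13.8979604644677	86.3920741312216	0.00368270725205276	1
L002	sporadic	63.2622452479787	14240.4059779885	0.456144685783718	165	summer	14.1636336995479	15.5179300021386	100.619273924659	945.195729768819	23.8809478192436	13.5687876166819	101.532043396492	0.0416359815574163	1
L003	discontinuous	65.8716837208718	107245.782016802	2.15257095612675	155	autumn	0.5	3.18317518486183	101.90653058856	1288.3644059684	6.65816544054648	18.7386657473887	88.3322659124218	0.0169159318433869	1
L003	discontinuous	65.8716837208718	107245.782016802	2.15257095612675	155	spring	11.2621741355587	13.0042981019193	101.703964098638	878.701252202568	13.125159697243	9.16875653042709	83.6826131914623	0.0247799216640146	1
L003	discontinuous	65.8716837208718	107245.782016802	2.15257095612675	155	summer	14.600035990819	16.2141319166656	99.3686338800427	1421.85804319753	5.36009429472867	20.9104045094541	107.009653755985	0.00913727440034218	1
L004	continuous	67.1982685756404	401.448066743808	0.461188782960013	150	autumn	5.98017001859529	9.03742602443852	100.718636138339	1394.72290714556	24.3840457887151	24.9687296043074	96.0551381245607	0.0522695823655396	1
L004	continuous	67.1982685756404	401.448066743808	0.461188782960013	150	spring	13.7166134817528	17.5386255305117	99.9263930567413	2289.89864690999	30.3995328429836	18.4622541019855	80.407860004976	0.0531829822848906	1
L004	continuous	67.1982685756404	401.448066743808	0.461188782960013	150	summer	16.9078511942102	16.2631065664181	101.328898085514	889.043480933581	17.8270124073176	20.0256460670471	105.447510871677	0.0294391686397546	1
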