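patient_id	chrom	start	stop	inheritance	neurodevelopmental_delay	asd	microcephaly	brain_anomalies	hearing_loss	iugr
Balci_2015_Basak_2015_pat3	chr2	59958420	60834298	de novo	+	na	-	+	-	-
Basak_2015_pat1_Hancarova_2013	chr2	60689977	61127979	de novo	+	+	+	-	-	-
Basak_2015_pat2	chr2	60029857	61059383	de novo	+	+	+	-	na	na
Fannemel_2014	chr2	61500346	61733075	de novo	+	na	-	-	+	-
Felix_2010	chr2	59139200	62488871	de novo	+	-	+	-	-	+
Ronzoni_2015	chr2	61659957	61762873	de novo	+	na	-	+	na	-
Shimbo_2017_pat1	chr2	58029768	61275725	de novo	+	-	-	+	-	-
Shimbo_2017_pat2	chr2	60676037	65731798	de novo	+	na	+	+	+	-
Shimbo_2017_pat3	chr2	61136131	66258735	de novo	+	-	+	+	+	+
Shimbo_2017_pat4	chr2	60013464	61136190	de novo	+	na	-	+	na	-
Shimojima_2015_pat1	chr2	61495220	61733075	de novo	+	na	+	+	-	+
Deleeuw_2007	chr2	58216217	61667426	de novo	+	-	+	na	-	-
Piccione_2012_pat1	chr2	60603496	61246496	de novo	+	-	-	-	-	na
Piccione_2012_pat2	chr2	60257496	62762496	de novo	+	na	+	+	+	na
Rajcan_Separovic_2007_pat1	chr2	56919993	63032165	de novo	+	+	+	+	-	+
Rajcan_Separovic_2007_pat2	chr2	55627639	63519476	de novo	+	+	+	+	+	-
Chabchoub_2008	chr2	61203258	61786583	de novo	+	-	-	-	-	-
Florisson_2013_pat1	chr2	55616146	62362249	de novo	+	na	+	+	-	na
Florisson_2013_pat2	chr2	58714795	65392528	de novo	+	na	+	na	+	na
Peter_2014	chr2	60689299	60830491	de novo	+	-	-	na	-	-
Bagheri_2016_pat1	chr2	55676099	65250541	de novo	+	+	+	+	-	+
Bagheri_2016_pat3	chr2	59017244	64379673	de novo	+	na	+	-	-	+
Bagheri_2016_pat4	chr2	60650589	61621631	de novo	+	na	-	na	-	na
Bagheri_2016_pat5	chr2	61060687	65653379	de novo	+	na	+	na	-	na
Bagheri_2016_pat6	chr2	61438499	61797959	de novo	+	-	+	na	-	+
Bagheri_2016_pat7	chr2	61585906	64253124	de novo	+	-	+	na	na	na
Bagheri_2016_pat8	chr2	61739766	62534498	de novo	+	na	-	na	-	-
Levy_2017_pat2	chr2	61671686	61777241	de novo	+	+	-	+	+	-
Levy_2017_pat3	chr2	60624940	61051867	de novo	+	+	-	+	-	-
Liang_2009	chr2	59241620	62385716	de novo	+	+	+	-	-	+
Ottolini_2015	chr2	60118706	61800462	de novo	+	na	+	na	na	+
Huctagowder_2012	chr2	60672255	63144695	de novo	+	na	+	+	+	+
id_723_Troina	chr2	63058141	63198230	de novo	+	-	-	na	-	-
id_7180_Troina	chr2	60294104	61618758	de novo	+	-	+	-	-	-
Jorgez_2014_pat4	chr2	60066496	66376960	de novo	+	na	-	+	na	na
Jorgez_2014_pat5	chr2	61056496	65656496	de novo	+	na	+	na	na	na
Jorgez_2014_pat6	chr2	61566496	64316496	de novo	+	na	-	na	na	na
Jorgez_2014_pat3	chr2	61126496	63516496	de novo	+	na	+	na	na	na
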