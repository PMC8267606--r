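item_id	subdomain	n_categories	a0	ag	c_1	c_2	c_3	c_4
it001	mood_cognition	5	1.1791252118874238	0.24616632342397934	-0.951014393777531386	-0.439391866925187946	0.259440936408837752	0.560577753746140606
it002	mood_cognition	5	1.3525150506579753	0.29225730948525652	-0.033803478561717712	0.312129254892698438	0.658061988347114601	1.003994721801530821
it003	mood_cognition	5	1.6014474644484338	0.28803174541572335	-2.457335195249337190	-1.238436026481451790	-0.277082451618295200	1.064498534929393614
it004	mood_cognition	5	1.3835324810369471	0.28097581983317993	-0.419933216647540186	0.321991291128574442	0.913007881641262231	1.366931457361476365
it005	mood_cognition	5	1.2873628204600565	0.22183162433671841	-2.167493932967290426	-1.840910071124468805	-1.305221111961600400	0.039025085630262815
it006	mood_cognition	5	2.2230115021352117	0.42609998344981598	-1.129412402782226765	0.031876023841493392	0.597746003083709843	1.163615982325926446
it007	mood_cognition	5	1.9776178227842363	0.29124946002722713	-4.956803464278593196	-1.376549812883271162	-0.733926126061886897	-0.234188788743570381
it008	mood_cognition	5	1.9992088744376642	0.31117694114854355	-3.520079815995246886	-3.014259491402803803	-0.774651912832148626	-0.078438121811246167
it009	mood_cognition	5	2.1813245580976455	0.51604057003493264	-3.389883523941520593	-1.324530728918903222	-0.764147227551208785	0.733653443806727812
it010	mood_cognition	5	1.3091947004660351	0.39565419298032606	-1.759993781713654837	-0.531348192652958073	-0.189429616440061954	0.587299351046451923
it011	arousal_reactivity	5	1.7709092596708151	0.45453732394464774	0.604783309158994364	1.567401324656952699	2.680611682321120792	3.407956044544677709
it012	arousal_reactivity	5	1.3775684124661727	0.19669407778573594	-1.838132473179150406	-1.170966141781000225	-0.823081166963483213	-0.145094262589676837
it013	arousal_reactivity	5	1.1805967647772759	0.21065563484429947	0.453872708496717070	1.011968835473674666	1.371275905175871612	1.671086732771188910
it014	arousal_reactivity	5	1.3150900716360083	0.39585417345309787	-1.537196984037518810	-1.193852912518525100	-0.219346803440802318	0.123997268078191281
it015	arousal_reactivity	5	1.4913237678052156	0.23588009946552724	-0.315016832238869393	0.062448894826566612	0.672711651501885610	1.192733376051827276
it016	arousal_reactivity	5	1.3026489340860239	0.37613592659126949	-0.960125944725941038	-0.573475912852572711	1.329023889059087749	1.667990377147155368
it017	arousal_reactivity	5	1.2050205463343637	0.24546303047663603	-0.164479034330263119	0.723109631634080152	1.030551355422786752	3.005776341412266905
it018	arousal_reactivity	5	2.0847415695840130	0.31111726407917506	-3.873451108716811753	-2.907584974509431763	0.411467890354730692	1.953949475898328458
it019	arousal_reactivity	5	1.4217890642590663	0.42910057309157507	1.266117814760632454	1.637400342382303364	2.270052564907806936	3.455786434690222286
it020	arousal_reactivity	5	1.2291923029650884	0.39138869825229444	-1.415714971851139925	-1.093215085146872712	-0.568537181501905242	0.030004073055269462
it021	avoidance	5	1.9306140221672115	0.53895341644229566	-1.153348169996772254	0.672320986424122302	1.173428590118396286	1.674536193812670160
it022	avoidance	5	1.3051525068577734	0.31403503839716934	-1.670966946034478040	-1.031621802846046876	-0.696021494490050241	-0.175841314161434281
it023	avoidance	5	1.8226560974675823	0.24485232925199626	2.908874958622699403	3.368632225610936448	4.211065573809689155	5.309633006608875050
it024	avoidance	5	1.1567810265066309	0.18748944013765528	-2.263648801870360217	-1.509744333705189456	-1.166386623102078302	0.405716589053843113
it025	avoidance	5	2.2355506783496124	0.62833048360139043	-2.528785052711275405	-1.860597545989362889	-0.090755710172108775	1.004505422215197896
it026	avoidance	5	1.2429641925840667	0.36443034144899955	-0.892574785052227204	0.477513474129643511	0.801335325019024824	2.393507263980578781
it027	avoidance	5	1.2394432827696866	0.27610273298125376	0.794046298462239175	1.517451879481413357	1.889912231132971243	2.207368170040504118
it028	avoidance	5	1.3342280539541616	0.28868309652388585	1.122347743986704227	2.042781661638840784	2.822050977635045754	3.163326382383260693
it029	avoidance	5	2.1526607188576032	0.45905066014031470	-0.964237899665741471	0.586825987598610599	1.203593481241983287	1.761800252322701876
it030	avoidance	5	1.6751285818666752	0.38883341101010221	-2.634571213263908085	1.876706791206114167	2.306623003050382259	2.736539214894650573
it031	intrusion	5	1.2514661064293437	0.31842360783082979	-1.110216843101924589	-0.787381648152800429	0.369165183019699361	1.161251521172304901
it032	intrusion	5	1.9605500351675931	0.53089953556011349	0.436659387307376412	0.944449375716314710	1.452239364125253118	3.725227987019751996
it033	intrusion	5	2.0933680839879854	0.33955136364453764	-2.122450238680907209	-1.500054697565020190	-0.325013126010252729	0.205168745120564877
it034	intrusion	5	1.4494972600311720	0.29822947192867544	0.684949304618694410	1.054914093886262005	2.816613282770912274	4.052602879670712532
it035	intrusion	5	1.3892111499260915	0.33949271340332365	0.640303328052685750	1.166619488764211621	1.635632400195533576	2.517562131056402919
it036	intrusion	5	2.0046598310706445	0.31701194784476455	-4.526672745305896584	-3.011729997529345670	-2.254387149392064416	-0.771276128086298196
it037	intrusion	5	1.3164188524987850	0.16801565442542374	-0.324972750129717991	0.229270095023810100	0.561044477638168670	1.126013244779591416
it038	intrusion	5	1.7602871306137542	0.43838401650880648	-2.195593086921815651	-0.039678471470459740	0.529309837862652510	1.515569258408250297
it039	intrusion	5	1.6995720903960367	0.44140369626700227	2.312725372234074150	2.751714446239006406	3.190703520243938662	3.629692594248870918
it040	intrusion	5	1.5041130013863488	0.44710881470065522	1.117088717642075402	1.509378646546903013	1.901668575451730847	3.616228605710550159
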