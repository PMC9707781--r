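wavelength_nm	L	M	S
400	0.21442236775492263	0.19513805056664918	0.7594781607331643
405	0.20267934742586272	0.18715307415257834	0.8223928937666531
410	0.19109654740503984	0.181707982931647	0.8798540822445606
415	0.18022684657646712	0.17951483476310143	0.9290775785802912
420	0.1706253715382235	0.1812313298799644	0.9672891895687264
425	0.16283839404931635	0.1874441589355881	0.9917734141298945
430	0.15739394924424432	0.19865256793054414	1
435	0.1547939398700361	0.21525130257232497	0.989870186337518
440	0.15550720274159818	0.23751251405492482	0.9600838651397136
445	0.15996279572794342	0.2655669373717988	0.9105587114561714
450	0.16854265922062228	0.2993855715816027	0.8427586671160889
455	0.18157285348476268	0.33876398154763515	0.759765526027921
460	0.1993127995495197	0.3833119163322945	0.6660008069729795
465	0.2219423616484722	0.43245091647417694	0.5666584515523743
470	0.24954717477609642	0.48542178385434426	0.4670437802494492
475	0.28210326767446003	0.5413022490275312	0.3720232283868373
480	0.31946263733996605	0.5990331916167889	0.28566217902423313
485	0.361341838057027	0.6574498698595499	0.21097863995220334
490	0.40731569543744395	0.7153133925155725	0.14971701094334622
495	0.4568178317667639	0.7713376031413609	0.10218114712160284
500	0.5091487846106547	0.8242078598805016	0.0672969383120288
505	0.5634912474711273	0.8725907834861836	0.04300252843126715
510	0.6189306243986263	0.9151375457725743	0.026836345528774386
515	0.6744780112519514	0.9504871255361431	0.016466770244410834
520	0.7290922189129775	0.9772794393155838	0.00999554689043209
525	0.7816977514121595	0.9941903613090369	0.006032988038615111
530	0.8311967911403237	1	0.003635124368359097
535	0.8764751036363075	0.99370055726493145	0.002193116087918027
540	0.9164041074223409	0.9746394565003863	0.001327677402604705
545	0.9498438206301948	0.9426778607018746	8.077270765157985e-4
550	0.9756535589216019	0.8983283777498127	4.943346216912532e-4
555	0.9927185257377382	0.8428265685144308	3.0454572167781357e-4
560	1	0.7780974560614128	1.8894731547662664e-4
565	0.9966137374360797	0.7066037996495113	1.180837373871432e-4
570	0.9819347251366184	0.6311000340031807	7.434482081607069e-5
575	0.9557167782200767	0.5543479332574337	4.715577481243487e-5
580	0.9182046848547671	0.47886107773126824	3.0132048455571744e-5
585	0.8702088967728615	0.4067300773282992	1.9395462242537324e-5
590	0.8131133487025883	0.3395482125628548	1.257492084780899e-5
595	0.7487991971822754	0.27842363179965646	8.210921972220274e-6
600	0.6794892407956771	0.22404260227511266	5.398869924822225e-6
605	0.6075416367046	0.17674392114188797	3.5741905338957876e-6
610	0.5352368081154472	0.136575925580789	2.382069270899239e-6
615	0.46460120956961765	0.10332845200788321	1.5979758862295004e-6
620	0.3972966490733224	0.07655285198892703	1.0788537096027887e-6
625	0.33458164370661925	0.055592793746984906	7.329414900556385e-7
630	0.2773310934949265	0.03964134481788403	5.009902388334767e-7
635	0.22608880764509368	0.02782142793822603	3.444945506370325e-7
640	0.18112609507289873	0.019271062454544446	2.3827023022001915e-7
645	0.14248733081026502	0.013212112841708378	1.657425900293311e-7
650	0.11001659897985885	0.00899038094504748	1.1593628130268437e-7
655	0.0833729297890485	0.006087075066058543	8.154004947147132e-8
660	0.062049168302650344	0.0041096141714539285	5.765484953726927e-8
665	0.04540715094694132	0.0027716246031259857	4.0979092741801116e-8
670	0.032731346842628774	0.00186998225854609	2.927522497282714e-8
675	0.02329163772652379	0.0012635880079843711	2.1018452222812876e-8
680	0.016400748316449804	8.558949648137102e-4	1.516409028272015e-8
685	0.011454863049121295	5.815293202661986e-4	1.0992614881116076e-8
690	0.00795341987867081	3.965278827120738e-4	8.005894553640678e-9
695	0.005500847980172636	2.7144570317044146e-4	5.85732546424871e-9
700	0.0037963826034768115	1.865992210034222e-4	4.3045439070589175e-9
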