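wavelength_nm	lens_transmittance	macular_transmittance_fovea
400	0.03713775669873029	0.8621632643583979
405	0.04959596432278327	0.7870644612829111
410	0.06661877461614218	0.7054106516002332
415	0.08936889922322841	0.6323972081927669
420	0.11897583499180607	0.5787926140625604
425	0.15634133427490293	0.5462749872593106
430	0.20191445684035195	0.5285173080256416
435	0.25549070946709845	0.5158396912731484
440	0.3160998664095273	0.5009490126529439
445	0.3820319639926209	0.48249769340182314
450	0.4510122655991765	0.46412781058918146
455	0.520488963043412	0.4509015773333702
460	0.5879629964511117	0.44668359215096315
465	0.6512820038566794	0.453557383034349
470	0.7088401782215716	0.4722595041036631
475	0.7596605266602157	0.502618141147483
480	0.8033698064616286	0.5436822708584569
485	0.8400980780107441	0.5936521236561488
490	0.8703413199075657	0.6498354702022778
495	0.8948203086972127	0.7088116767468168
500	0.9143579514236498	0.7668606705382733
505	0.9297857334752212	0.820558399297518
510	0.9418809742309994	0.8673337474052617
515	0.9513311054630245	0.9057906598973726
520	0.9587187844697417	0.9357136967264174
525	0.9645213667134482	0.9578140752199445
530	0.9691191326031219	0.9733541018662855
535	0.97280797330954	0.983786103543381
540	0.9758135556392753	0.9904880168688548
545	0.9783050954447158	0.994616708485952
550	0.9804077078910352	0.9970595284004551
555	1	0.9984493340792203
560	1	0.999210331799372
565	1	0.9996116217225643
570	1	0.9998155050782441
575	1	0.9999153448460911
580	1	0.9999624791173507
585	1	0.9999839361657195
590	1	0.9999933566845832
595	1	0.9999973461189503
600	1	0.9999989759064661
605	1	0.99999961826702
610	1	0.9999998625509453
615	1	0.9999999521936154
620	1	0.9999999839382769
625	1	0.9999999947873272
630	1	0.9999999983658538
635	1	0.9999999995051387
640	1	0.9999999998552435
645	1	0.999999999959097
650	1	0.9999999999888356
655	1	0.9999999999970565
660	1	0.9999999999992503
665	1	0.9999999999998156
670	1	0.9999999999999561
675	1	0.9999999999999899
680	1	0.9999999999999978
685	1	0.9999999999999996
690	1	0.9999999999999999
695	1	1
700	1	1
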