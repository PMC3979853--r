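transect,year,visit,day_of_season,rain_mm,temp_c,wind
1,1,1,12,0,13.871127730312928,1.8247845006642147
1,1,2,14,8.8337509077370928,18.723348719586184,2.0945912171957417
1,1,3,16,5.3625418616641056,12.156794127945691,7.8029058924604575
1,2,1,9,0,20.303933422667857,6.409849048294376
1,2,2,11,0,17.751983332646418,1.5245809523664955
1,2,3,13,0,12.315673773436842,2.7551107385492508
2,1,1,25,0.73843394033610821,12.935502165124809,6.1080427166874793
2,1,2,27,2.3551758211106062,12.004548230281186,0.71177908726130446
2,1,3,29,2.1522594057023525,8.6782758070764245,5.8945457998983626
2,2,1,21,0,17.57225687251071,4.4692125033642522
2,2,2,23,2.9207579380083568,18.378227183982624,3.6651507115737316
2,2,3,25,0,14.404894797380074,5.9138969169082394
3,1,1,30,0,15.463847831221809,2.4086705730741347
3,1,2,32,0.36966819591861555,12.59519739261315,4.1960231728612971
3,1,3,34,0,14.864456422434881,1.8476698515780874
3,2,1,11,7.7748140465832725,11.88527774438392,1.6387537025610937
3,2,2,13,0,19.678599341973417,6.4240860165099836
3,2,3,15,5.6690866198755279,12.348958192340788,4.1191389481735241
4,1,1,25,5.6760345172501578,15.231421222819941,1.9815318458839555
4,1,2,27,0,17.51160407751011,0.81461391661128457
4,1,3,29,0,15.299776667329311,3.2252374261531251
4,2,1,26,0,15.908185009708561,2.2383391164490876
4,2,2,28,1.8505238182842731,11.524066735390102,3.0280002522771907
4,2,3,30,1.4337362807716443,19.814620076947698,7.5982523813031815
5,1,1,16,0,11.693995406919827,2.6493294673726466
5,1,2,18,0.69996342202947426,12.528842978900798,5.6745754652923468
5,1,3,20,0,18.628328155358936,1.3395620722354069
5,2,1,8,0,17.371164447500139,3.7215011222316354
5,2,2,10,0,11.701051392751509,3.3832994173614757
5,2,3,12,0,13.735652322109566,0.97588495326940594
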