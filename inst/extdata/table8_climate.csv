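breed,breed_id,Location,Country,Continent,N,LAT,LON,MINaT,MAXaT,MThm,ANT,TW,TAR,MxR,MiR,HrA,HrMx,HrMi,THI,CTY
Akkaraman,AKA,Konya,Turkey,Asia,23,37.6,32.3,-0.2,23.1,30.1,11.5,23.3,315,41,4,60,80,40,22.02,SA
Kazakh Arkhar-Merino,ARME,Alma Ata,Kazakhstan,Asia,18,43.45,77.04,-6.1,23.6,29.4,9.1,29.7,653,107,26,62,77,45,22.52,SD
Assaf,AS,Haifa,Israel,Asia,30,31.86,35.21,14.0,29.9,40.0,20.7,13.4,534,148,0,68,72,60,28.36,SD
Awassi,AW,Haifa,Israel,Asia,30,31.86,35.21,14.0,27.4,40.0,20.7,13.4,534,148,0,68,72,60,26.11,SD
Bajdarak,BAJ,Irkutsk,Russia,Asia,22,51.83,107.43,-18.8,17.5,34.0,0.0,36.3,468,120,9,75,86,58,17.26,SA
Bni Guil,BNI,Fez,Morocco,Africa,27,33.56,4.59,9.6,27.1,35.8,17.8,17.5,537,85,1,67,79,56,25.8,SD
Boujaad,BOUJ,Marrakech,Morocco,Africa,24,32.86,-6.96,12.2,28.3,39.0,19.6,16.1,282,41,1,58,66,47,26.49,SA
Bozakh,BOZ,Kirovabad,Azerbaijan,Asia,24,40.53,46.02,2.7,25.1,30.9,13.9,22.4,294,51,11,65,78,53,23.94,SA
Caucasian,CAUC,Astrakan,Russia,Asia,25,45.71,42.88,-5.5,25.2,30.6,10.0,30.7,216,25,10,70,86,54,24.2,A
Churra,Ch,León,Spain,Europe,23,42.58,-5.65,3.1,19.6,37.0,10.9,16.5,555,70,24,68,83,55,19.08,SD
Churra Lebrijana,Cl,Jerez,Spain,Europe,26,36.75,-6.06,10.7,25.7,38.0,17.7,15.0,587,109,2,67,79,54,24.54,SD
Churra Tensina,Ct,Huesca,Spain,Europe,33,42.08,-0.33,4.9,23.4,37.0,13.6,18.5,534,62,20,63,81,48,22.37,SD
Daglic,DGL,Eskisehir,Turkey,Asia,24,38.5,30.3,-0.1,21.4,28.6,11.1,21.5,388,51,9,70,84,59,20.75,SA
Kazakh Edilbai,EDIL,Aktjubinsk,Kazakhstan,Asia,30,52.32,77.03,-14.1,22.4,39.0,4.7,36.5,311,33,19,66,82,50,21.56,SA
Ivesi,IV,Diyarbakir,Turkey,Asia,15,37.5,40.1,1.5,31.0,38.1,14.9,29.5,498,76,1,55,77,29,28.68,SA
Russian Karakul,KAR,Astradan,Russia,Asia,15,45.37,46.04,-5.5,25.2,42.0,10.0,30.7,216,25,10,70,86,54,24.2,A
Moldavian Karakul,KARM,Kisinev,Moldavia,Europe,15,46.93,28.75,-3.3,20.9,37.0,9.6,24.2,547,75,27,73,86,62,20.36,SD
Karabakh,KRB,Kirovabad,Azerbaijan,Asia,24,39.82,46.7,-0.4,23.6,38.0,11.9,24.0,294,51,11,65,78,53,22.6,SA
Karachai,KRC,Krasnojarsk,Azerbaijan,Asia,28,43.04,44.21,-16.0,18.2,37.0,0.8,34.2,450,79,12,68,76,53,17.82,SA
Karayaka,KRY,Samsun,Turkey,Asia,22,41.2,36.2,6.9,22.7,26.2,14.3,15.8,692,89,29,72,79,65,21.98,SD
Kivircik,KVR,Bursa,Turkey,Asia,16,40.1,29.0,5.2,24.1,30.3,14.4,18.9,706,118,16,72,78,62,23.26,SD
Finnsheep,L,Jyvaskyla,Finland,Europe,30,62.31,27.17,-10.0,15.7,20.8,2.6,25.7,640,91,30,80,91,65,15.62,SD
Latxa,LX,Vitoria,Spain,Europe,41,42.88,-2.73,4.7,19.1,30.0,11.4,14.4,782,89,42,75,84,71,18.74,SD
D’Man,MAN,Ouarzazate,Morocco,Africa,26,30.93,-6.9,9.3,29.5,40.0,18.9,20.2,110,19,1,41,64,22,26.74,A
Spanish Merino,ME,Cáceres,Spain,Europe,29,39.29,-6.22,8.2,25.6,39.0,16.0,17.4,488,65,4,57,76,35,24.11,SA
Manchega,MNCH,Albacete,Spain,Europe,60,38.95,-1.85,5.0,24.1,38.0,13.5,19.1,367,52,9,63,79,44,22.99,SA
Olkuska,OL,Cracovia,Poland,Europe,30,49.78,21.34,-2.9,19.3,30.0,8.6,22.2,679,95,33,80,87,72,19.0,SD
Pramenka,PRAM,Belgrado,Servia,Europe,29,44.74,20.44,0.5,21.7,28.3,11.8,21.2,694,95,42,69,82,60,21.0,SD
Rasa Aragonesa,RA,Zaragoza,Spain,Europe,42,41.66,-1.01,6.2,24.3,35.0,14.6,18.1,314,38,15,65,77,53,23.23,SA
Sakiz,SZ,Izmir,Chios,Asia,26,38.3,27.1,8.6,22.5,32.7,17.7,18.9,693,153,4,62,72,49,21.55,SD
Valle del Belice,VdB,Palermo,Italy,Europe,29,37.69,13.02,11.6,25.4,30.2,18.2,13.8,654,106,5,69,75,63,24.34,SD
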