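#! meta ligand: SeDG
#! meta temperature_K: 303
#! meta buffer: 10 mM KPi pH 7.4
#! meta true_kd_uM: 123
#! meta seed: 42
point_index,protein_total_uM,ligand_total_uM,residue_id,residue_name,delta_H_ppm,delta_N_ppm,quality
1,270,0,156,THR,8.4347419168942945,122.90611342209679,ok
1,270,0,157,SER,7.0368706036572082,116.49223993796082,ok
1,270,0,158,HIS,9.0727262568226745,115.53565720308508,ok
1,270,0,159,PHE,8.5132657252099229,111.33634486587337,ok
1,270,0,160,ASN,7.5078085366462819,115.04866692657143,ok
1,270,0,161,LYS,7.4357877509678172,114.38643546221017,ok
1,270,0,162,ARG,7.7580230439948776,122.67784232751869,ok
1,270,0,174,ASN,9.0358106819231736,104.07047652153891,ok
1,270,0,175,THR,7.1980368474277538,110.41300697121453,ok
1,270,0,176,LYS,9.1998745718018942,126.55782220912781,ok
1,270,0,177,PHE,8.1626097393084471,118.60778422241104,ok
1,270,0,184,GLU,7.6545732907854029,129.20278414826245,ok
1,270,0,222,ASN,9.2512222785977745,110.84736522638293,ok
1,270,0,230,ASN,7.6494424224663655,114.48081572000996,ok
2,270,30.749999999999996,156,THR,8.4317333573272126,122.93159965106483,ok
2,270,30.749999999999996,157,SER,7.0392719007961402,116.49306408679298,ok
2,270,30.749999999999996,158,HIS,9.0821097362215237,115.63266514935427,ok
2,270,30.749999999999996,159,PHE,8.509356649674281,111.379963311144,ok
2,270,30.749999999999996,160,ASN,7.5047886266589376,115.02900411646384,ok
2,270,30.749999999999996,161,LYS,7.4386402266914606,114.40696963803346,ok
2,270,30.749999999999996,162,ARG,7.7543867228118426,122.63666453182485,ok
2,270,30.749999999999996,174,ASN,9.0431156251963962,104.15075611809142,ok
2,270,30.749999999999996,175,THR,7.1997580178966842,110.43350511904403,ok
2,270,30.749999999999996,176,LYS,9.2085312020065491,126.5695032332423,ok
2,270,30.749999999999996,177,PHE,8.1637903869225301,118.63376386069002,ok
2,270,30.749999999999996,184,GLU,7.6537154511929408,129.25289248220096,ok
2,270,30.749999999999996,222,ASN,9.2572991191145881,110.89619375414355,ok
2,270,30.749999999999996,230,ASN,7.6464736738296111,114.51216145455885,ok
3,270,77.332155925500501,156,THR,8.4329201947096628,122.92029129528308,ok
3,270,77.332155925500501,157,SER,7.0367200102480796,116.46991565738625,ok
3,270,77.332155925500501,158,HIS,9.0986453014430975,115.67221345466567,ok
3,270,77.332155925500501,159,PHE,8.5198432749736117,111.37830761331362,ok
3,270,77.332155925500501,160,ASN,7.5155038073430935,115.06570128269355,ok
3,270,77.332155925500501,161,LYS,7.4347821472491855,114.4240378200069,ok
3,270,77.332155925500501,162,ARG,7.756009910246596,122.62275767537621,ok
3,270,77.332155925500501,174,ASN,9.0583003838384677,104.24818056063513,ok
3,270,77.332155925500501,175,THR,7.2071364540955924,110.4712269319261,ok
3,270,77.332155925500501,176,LYS,9.213003556923999,126.60169071844369,ok
3,270,77.332155925500501,177,PHE,8.1551715847001063,118.63249404772394,ok
3,270,77.332155925500501,184,GLU,7.6611012742980495,129.27359407786409,ok
3,270,77.332155925500501,222,ASN,9.2636028547706193,110.93429955070545,ok
3,270,77.332155925500501,230,ASN,7.6492778854029027,114.50143482237149,ok
4,270,194.48007610035535,156,THR,8.4335163264714001,122.91772656787101,ok
4,270,194.48007610035535,157,SER,7.0365465903458473,116.43950644309162,ok
4,270,194.48007610035535,158,HIS,9.126281868597232,115.88205209540325,ok
4,270,194.48007610035535,159,PHE,8.5271202437232958,111.44540895504748,ok
4,270,194.48007610035535,160,ASN,7.5196318213191438,115.14317103811359,ok
4,270,194.48007610035535,161,LYS,7.4388882025234428,114.36014245292894,ok
4,270,194.48007610035535,162,ARG,7.7541371075947731,122.65000125768131,ok
4,270,194.48007610035535,174,ASN,9.0943297264528749,104.46900484727804,ok
4,270,194.48007610035535,175,THR,7.2272258109224481,110.65279809255482,ok
4,270,194.48007610035535,176,LYS,9.2310142825102783,126.73205870232717,ok
4,270,194.48007610035535,177,PHE,8.1631514550395838,118.62765360879499,ok
4,270,194.48007610035535,184,GLU,7.6757222689054654,129.40693976997861,ok
4,270,194.48007610035535,222,ASN,9.274543246538224,111.00315148510386,ok
4,270,194.48007610035535,230,ASN,7.6505531014945829,114.50895061030123,ok
5,270,489.09149819173592,156,THR,8.4333585776321112,122.92827785403526,ok
5,270,489.09149819173592,157,SER,7.0381796657731588,116.46224641964187,ok
5,270,489.09149819173592,158,HIS,9.1651091702044969,116.16814785800032,ok
5,270,489.09149819173592,159,PHE,8.5373436034997621,111.51636708522325,ok
5,270,489.09149819173592,160,ASN,7.5310393683072183,115.19867860582386,ok
5,270,489.09149819173592,161,LYS,7.436370461129731,114.39226772046737,ok
5,270,489.09149819173592,162,ARG,7.7561636474547306,122.64038014316692,ok
5,270,489.09149819173592,174,ASN,9.1378948240253877,104.70837815744601,ok
5,270,489.09149819173592,175,THR,7.2491713303786529,110.80324041370207,ok
5,270,489.09149819173592,176,LYS,9.2592309997616891,126.8981757939076,ok
5,270,489.09149819173592,177,PHE,8.1606716962395041,118.62918603049697,ok
5,270,489.09149819173592,184,GLU,7.6945464480705965,129.47209867604104,ok
5,270,489.09149819173592,222,ASN,9.2912326536975822,111.14108176691174,ok
5,270,489.09149819173592,230,ASN,7.6514417563257338,114.50452708597253,ok
6,270,1229.9999999999998,156,THR,8.4299137621228653,122.92064309350656,ok
6,270,1229.9999999999998,157,SER,7.0378196272267788,116.45523495344028,ok
6,270,1229.9999999999998,158,HIS,9.1977731484816214,116.34036976605204,ok
6,270,1229.9999999999998,159,PHE,8.5412244813238622,111.54636241386531,ok
6,270,1229.9999999999998,160,ASN,7.5370458704102576,115.24169821082532,ok
6,270,1229.9999999999998,161,LYS,7.437161992995363,114.3957535049117,ok
6,270,1229.9999999999998,162,ARG,7.7565363574756692,122.64648948259516,ok
6,270,1229.9999999999998,174,ASN,9.161453647334703,104.85908935904456,ok
6,270,1229.9999999999998,175,THR,7.2633862257809652,110.89247386398287,ok
6,270,1229.9999999999998,176,LYS,9.2689582165784881,127.01195495802095,ok
6,270,1229.9999999999998,177,PHE,8.1630254140196108,118.64180027095975,ok
6,270,1229.9999999999998,184,GLU,7.7038841766569028,129.60443733043354,ok
6,270,1229.9999999999998,222,ASN,9.2986504919431834,111.16146143017187,ok
6,270,1229.9999999999998,230,ASN,7.6497582069249219,114.51909300595162,ok
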