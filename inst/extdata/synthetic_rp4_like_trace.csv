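time_ms,value
2,-0.25003
4,-0.7032
6,-0.58458
8,-0.20576
10,0.35088
12,0.47812
14,0.51371
16,0.53122
18,0.38214
20,-0.32222
22,-0.22706
24,0.07572
26,0.2445
28,0.01924
30,0.15634
32,-0.05463
34,-0.32427
36,-0.3044
38,-0.26363
40,-0.10549
42,-0.16507
44,0.50032
46,0.50665
48,0.31193
50,-0.01899
52,0.48408
54,0.53408
56,0.32312
58,-0.23984
60,-0.63139
62,-0.42646
64,-0.36046
66,-0.40819
68,-0.16783
70,-0.19654
72,0.22129
74,-0.23497
76,-0.36288
78,-0.21654
80,-0.13132
82,0.21448
84,-0.35515
86,-0.61737
88,-0.01464
90,-0.07259
92,-0.49494
94,-0.27568
96,0.11388
98,0.1786
100,-0.15982
102,-0.45327
104,-0.16614
106,0.12602
108,0.48279
110,0.15994
112,0.24258
114,0.34813
116,0.03315
118,-0.51743
120,-0.77333
122,-0.53804
124,0.141
126,0.1562
128,0.30409
130,0.14964
132,0.0803
134,0.19187
136,0.26857
138,0.2006
140,-0.01523
142,-0.24205
144,-0.34245
146,0.1932
148,0.5939
150,0.4905
152,-0.39135
154,-0.16219
156,0.01317
158,0.07975
160,-0.05236
162,0.1712
164,-0.27599
166,0.08474
168,0.01184
170,0.16045
172,-0.13502
174,-0.22482
176,-0.23879
178,-0.18872
180,0.2431
182,0.67514
184,0.91432
186,0.58439
188,0.78291
190,0.6393
192,3.64587
194,-0.0261
196,-0.38136
198,-0.15161
200,0.02369
202,0.07664
204,0.31116
206,0.36477
208,-0.26012
210,2.61559
212,-0.18503
214,-0.04267
216,0.39031
218,0.11586
220,0.0219
222,-0.31121
224,-0.47723
226,0.08855
228,-0.0777
230,-0.46864
232,-0.69471
234,0.18186
236,-0.13058
238,-0.20428
240,-0.2561
242,-0.34205
244,-0.0106
246,-0.0616
248,0.21122
250,0.60387
252,0.67696
254,0.10181
256,-0.55746
258,-0.85563
260,-0.66167
262,-0.13577
264,0.98585
266,1.46761
268,1.29069
270,1.13953
272,1.68792
274,1.99238
276,5.14334
278,1.87753
280,1.80787
282,1.65017
284,1.80024
286,1.2839
288,1.33994
290,1.43259
292,1.57923
294,1.78875
296,1.64902
298,1.652
300,1.0006
302,0.29249
304,-0.16246
306,0.07894
308,1.88892
310,-0.33764
312,-0.17681
314,0.21186
316,3.54019
318,0.01608
320,2.30227
322,0.05917
324,-0.02918
326,-0.06378
328,-0.48072
330,-0.49599
332,0.09117
334,0.64614
336,0.72747
338,0.53172
340,0.34599
342,-0.23784
344,-0.08433
346,-0.0154
348,-0.34817
350,0.20966
352,0.31132
354,0.23653
356,0.1817
358,0.20049
360,-0.2382
362,-0.17358
364,-0.05252
366,-0.41645
368,-0.04152
370,0.07907
372,0.47406
374,0.13224
376,-0.07203
378,-0.04532
380,0.18447
382,0.16929
384,0.26629
386,0.01763
388,-0.09197
390,3.27986
392,0.24027
394,-0.14061
396,-0.24122
398,0.27781
400,-0.13408
402,-0.00261
404,-0.15438
406,2.55853
408,0.25298
410,0.17068
412,0.35841
414,-0.154
416,-0.27644
418,0.08174
420,0.36321
422,0.53237
424,0.27119
426,-0.39774
428,-0.18692
430,0.17184
432,0.39855
434,0.65742
436,0.32161
438,0.43588
440,-0.61418
442,-0.68072
444,1.85846
446,-0.1526
448,-0.17534
450,-0.1818
452,0.22007
454,0.76787
456,0.9888
458,0.75879
460,3.68143
462,0.71487
464,0.73045
466,0.6006
468,0.15766
470,0.07085
472,0.18249
474,-0.03731
476,-0.36006
478,-0.03127
480,-0.03342
482,-0.02355
484,0.15065
486,-0.4718
488,-0.49533
490,-0.15042
492,0.22542
494,-0.02898
496,-0.36969
498,0.01733
500,-0.10204
502,-0.27252
504,0.30075
506,0.2561
508,0.34278
510,-0.17794
512,0.27364
514,0.16575
516,2.73291
518,-0.21816
520,-0.9966
522,-0.91994
524,-0.85765
526,-0.79326
528,-0.28056
530,0.20646
532,0.04117
534,-0.14366
536,-0.15169
538,-0.23037
540,-0.27964
542,-0.08256
544,-0.40723
546,-0.44078
548,-0.11841
550,-0.06477
552,-0.15479
554,-0.12043
556,-0.14181
558,-0.1107
560,-0.17606
562,-0.35236
564,-0.1939
566,0.21452
568,0.17672
570,-0.04721
572,-0.34405
574,-0.20945
576,-0.16206
578,0.10747
580,0.31338
582,0.12548
584,0.221
586,0.08866
588,-0.12069
590,-0.19474
592,0.31721
594,0.41082
596,0.48385
598,0.04709
600,-0.31041
602,0.16348
604,-0.02392
606,0.07095
608,3.48158
610,-0.38996
612,-0.00412
614,-0.75894
616,-1.15505
618,-1.26967
620,-0.90287
622,-0.28761
624,0.23948
626,-0.10165
628,-0.0391
630,0.06116
632,0.23159
634,-0.04889
636,0.11364
638,-0.17721
640,-0.16043
642,0.49299
644,-0.10314
646,-0.03543
648,-0.58834
650,-0.42605
652,-0.1865
654,-0.0987
656,-0.23519
658,-0.0605
660,-0.44776
662,-0.3556
664,-0.38976
666,0.14673
668,-0.07514
670,-0.64384
672,-0.2636
674,0.17309
676,0.35669
678,-0.00728
680,-0.3589
682,-0.06257
684,0.34557
686,0.35947
688,0.41696
690,-0.33335
692,-0.65764
694,-0.52966
696,-0.11236
698,0.11623
700,0.48316
702,0.01446
704,-0.19403
706,-0.28962
708,-0.08227
710,-0.12513
712,-0.12669
714,-0.42322
716,-0.85888
718,-0.91805
720,-0.38839
722,-0.41044
724,0.03999
726,0.39565
728,0.29965
730,-0.29921
732,0.01409
734,0.05703
736,-0.41782
738,-0.58635
740,-0.32176
742,0.22798
744,0.01769
746,-0.15239
748,-0.45744
750,-0.97286
752,-1.31768
754,-1.78929
756,-2.24983
758,-2.8723
760,-2.83866
762,-2.84448
764,-2.75436
766,-2.63853
768,-2.83193
770,-3.15475
772,-3.36211
774,-2.89009
776,-2.7209
778,-3.0476
780,-3.27932
782,-3.62989
784,-3.96825
786,-4.33694
788,-4.42442
790,-4.42134
792,-4.37574
794,-3.65223
796,-3.4131
798,-3.60236
800,-3.56131
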