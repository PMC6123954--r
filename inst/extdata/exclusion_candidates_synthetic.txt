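TTN
SIRPA
OBSCN
MACF1
HSPG2
NEB
MUC4
MUC16
MUC5B
MUC12
AHNAK
AHNAK2
FLG
HLA-A
HLA-B
HLA-DRB1
PRAMEF1
PRAMEF2
NBPF1
NBPF10
PDE4DIP
CDC27
FCGBP
HYDIN
SYNE1
SYNE2
DNAH5
DNAH11
USP6
ZNF717
TPTE
ANKRD36
ANKRD36C
FRG1
LILRA6
LILRB3
KRTAP4-11
KRTAP5-5
PABPC1
PABPC3
HRNR
TCHH
PLIN4
CCDC168
ZNF806
GOLGA6L2
TRIM49
TRIM64
OR8U1
OR4C5
CTBP2
HERC2P2
LRRC37A
FAM104B
POTEE
POTEF
RGPD3
RGPD4
SSPO
SYNEXC001
SYNEXC002
SYNEXC003
SYNEXC004
SYNEXC005
SYNEXC006
SYNEXC007
SYNEXC008
SYNEXC009
SYNEXC010
SYNEXC011
SYNEXC012
SYNEXC013
SYNEXC014
SYNEXC015
SYNEXC016
SYNEXC017
SYNEXC018
SYNEXC019
SYNEXC020
SYNEXC021
SYNEXC022
SYNEXC023
SYNEXC024
SYNEXC025
SYNEXC026
SYNEXC027
SYNEXC028
SYNEXC029
SYNEXC030
SYNEXC031
SYNEXC032
SYNEXC033
SYNEXC034
SYNEXC035
SYNEXC036
SYNEXC037
SYNEXC038
SYNEXC039
SYNEXC040
SYNEXC041
SYNEXC042
SYNEXC043
SYNEXC044
SYNEXC045
SYNEXC046
SYNEXC047
SYNEXC048
SYNEXC049
SYNEXC050
SYNEXC051
SYNEXC052
SYNEXC053
SYNEXC054
SYNEXC055
SYNEXC056
SYNEXC057
SYNEXC058
SYNEXC059
SYNEXC060
SYNEXC061
SYNEXC062
SYNEXC063
SYNEXC064
SYNEXC065
SYNEXC066
SYNEXC067
SYNEXC068
SYNEXC069
SYNEXC070
SYNEXC071
SYNEXC072
SYNEXC073
SYNEXC074
SYNEXC075
SYNEXC076
SYNEXC077
SYNEXC078
SYNEXC079
SYNEXC080
SYNEXC081
SYNEXC082
SYNEXC083
SYNEXC084
SYNEXC085
SYNEXC086
SYNEXC087
SYNEXC088
SYNEXC089
SYNEXC090
SYNEXC091
SYNEXC092
SYNEXC093
SYNEXC094
SYNEXC095
SYNEXC096
SYNEXC097
SYNEXC098
SYNEXC099
SYNEXC100
SYNEXC101
SYNEXC102
SYNEXC103
SYNEXC104
SYNEXC105
SYNEXC106
SYNEXC107
SYNEXC108
SYNEXC109
SYNEXC110
SYNEXC111
SYNEXC112
SYNEXC113
SYNEXC114
SYNEXC115
SYNEXC116
SYNEXC117
SYNEXC118
SYNEXC119
SYNEXC120
SYNEXC121
SYNEXC122
SYNEXC123
SYNEXC124
SYNEXC125
SYNEXC126
SYNEXC127
SYNEXC128
SYNEXC129
SYNEXC130
SYNEXC131
SYNEXC132
SYNEXC133
SYNEXC134
SYNEXC135
SYNEXC136
SYNEXC137
SYNEXC138
SYNEXC139
SYNEXC140
SYNEXC141
SYNEXC142
SYNEXC143
SYNEXC144
SYNEXC145
SYNEXC146
SYNEXC147
SYNEXC148
SYNEXC149
SYNEXC150
SYNEXC151
SYNEXC152
SYNEXC153
SYNEXC154
SYNEXC155
SYNEXC156
SYNEXC157
SYNEXC158
SYNEXC159
SYNEXC160
SYNEXC161
SYNEXC162
SYNEXC163
SYNEXC164
SYNEXC165
SYNEXC166
SYNEXC167
SYNEXC168
SYNEXC169
SYNEXC170
SYNEXC171
SYNEXC172
SYNEXC173
SYNEXC174
SYNEXC175
SYNEXC176
SYNEXC177
SYNEXC178
SYNEXC179
SYNEXC180
SYNEXC181
SYNEXC182
SYNEXC183
SYNEXC184
SYNEXC185
SYNEXC186
SYNEXC187
SYNEXC188
SYNEXC189
SYNEXC190
SYNEXC191
SYNEXC192
SYNEXC193
SYNEXC194
SYNEXC195
SYNEXC196
SYNEXC197
SYNEXC198
SYNEXC199
SYNEXC200
SYNEXC201
SYNEXC202
SYNEXC203
SYNEXC204
SYNEXC205
SYNEXC206
SYNEXC207
SYNEXC208
SYNEXC209
SYNEXC210
SYNEXC211
SYNEXC212
SYNEXC213
SYNEXC214
SYNEXC215
SYNEXC216
SYNEXC217
SYNEXC218
SYNEXC219
SYNEXC220
SYNEXC221
SYNEXC222
SYNEXC223
SYNEXC224
SYNEXC225
SYNEXC226
SYNEXC227
SYNEXC228
SYNEXC229
SYNEXC230
SYNEXC231
SYNEXC232
SYNEXC233
SYNEXC234
SYNEXC235
SYNEXC236
SYNEXC237
SYNEXC238
SYNEXC239
SYNEXC240
SYNEXC241
SYNEXC242
SYNEXC243
SYNEXC244
SYNEXC245
SYNEXC246
SYNEXC247
SYNEXC248
SYNEXC249
SYNEXC250
SYNEXC251
SYNEXC252
SYNEXC253
SYNEXC254
SYNEXC255
SYNEXC256
SYNEXC257
SYNEXC258
SYNEXC259
SYNEXC260
SYNEXC261
SYNEXC262
SYNEXC263
SYNEXC264
SYNEXC265
SYNEXC266
SYNEXC267
SYNEXC268
SYNEXC269
SYNEXC270
SYNEXC271
SYNEXC272
SYNEXC273
SYNEXC274
SYNEXC275
SYNEXC276
SYNEXC277
SYNEXC278
SYNEXC279
SYNEXC280
SYNEXC281
SYNEXC282
SYNEXC283
SYNEXC284
SYNEXC285
SYNEXC286
SYNEXC287
SYNEXC288
SYNEXC289
SYNEXC290
SYNEXC291
SYNEXC292
SYNEXC293
SYNEXC294
SYNEXC295
SYNEXC296
SYNEXC297
SYNEXC298
SYNEXC299
SYNEXC300
SYNEXC301
SYNEXC302
SYNEXC303
SYNEXC304
SYNEXC305
SYNEXC306
SYNEXC307
SYNEXC308
SYNEXC309
SYNEXC310
SYNEXC311
SYNEXC312
SYNEXC313
SYNEXC314
SYNEXC315
SYNEXC316
SYNEXC317
SYNEXC318
SYNEXC319
SYNEXC320
SYNEXC321
SYNEXC322
SYNEXC323
SYNEXC324
SYNEXC325
SYNEXC326
SYNEXC327
SYNEXC328
SYNEXC329
SYNEXC330
SYNEXC331
SYNEXC332
SYNEXC333
SYNEXC334
SYNEXC335
SYNEXC336
SYNEXC337
SYNEXC338
SYNEXC339
SYNEXC340
SYNEXC341
SYNEXC342
SYNEXC343
SYNEXC344
SYNEXC345
SYNEXC346
SYNEXC347
SYNEXC348
SYNEXC349
SYNEXC350
SYNEXC351
SYNEXC352
SYNEXC353
SYNEXC354
SYNEXC355
SYNEXC356
SYNEXC357
SYNEXC358
SYNEXC359
SYNEXC360
SYNEXC361
SYNEXC362
SYNEXC363
SYNEXC364
SYNEXC365
SYNEXC366
SYNEXC367
SYNEXC368
SYNEXC369
SYNEXC370
SYNEXC371
SYNEXC372
SYNEXC373
SYNEXC374
SYNEXC375
SYNEXC376
SYNEXC377
SYNEXC378
SYNEXC379
SYNEXC380
SYNEXC381
SYNEXC382
SYNEXC383
SYNEXC384
SYNEXC385
SYNEXC386
SYNEXC387
SYNEXC388
SYNEXC389
SYNEXC390
SYNEXC391
SYNEXC392
SYNEXC393
SYNEXC394
SYNEXC395
SYNEXC396
SYNEXC397
SYNEXC398
SYNEXC399
SYNEXC400
SYNEXC401
SYNEXC402
SYNEXC403
SYNEXC404
SYNEXC405
SYNEXC406
SYNEXC407
SYNEXC408
SYNEXC409
SYNEXC410
SYNEXC411
SYNEXC412
SYNEXC413
SYNEXC414
SYNEXC415
SYNEXC416
SYNEXC417
SYNEXC418
SYNEXC419
SYNEXC420
SYNEXC421
SYNEXC422
SYNEXC423
SYNEXC424
SYNEXC425
SYNEXC426
SYNEXC427
SYNEXC428
SYNEXC429
SYNEXC430
SYNEXC431
SYNEXC432
SYNEXC433
SYNEXC434
SYNEXC435
SYNEXC436
SYNEXC437
SYNEXC438
SYNEXC439
SYNEXC440
SYNEXC441
SYNEXC442
SYNEXC443
SYNEXC444
SYNEXC445
SYNEXC446
SYNEXC447
SYNEXC448
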