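gene	weight
G0001	-0.5263
G0002	-0.95
G0003	-0.0346
G0004	0.2779
G0005	-0.7167
G0006	-0.2378
G0007	-0.9277
G0008	-0.7383
G0009	-0.4318
G0010	-0.2042
G0011	0.9216
G0012	0.5043
G0013	0.589
G0014	0.5979
G0015	0.9739
G0016	0.1344
G0017	-0.146
G0018	-0.5237
G0019	0.9185
G0020	-0.0804
G0021	0.6581
G0022	-0.7734
G0023	0.9863
G0024	0.3276
G0025	0.2445
G0026	-0.9927
G0027	0.0909
G0028	-0.4744
G0029	0.6186
G0030	-0.5137
G0031	-0.6332
G0032	0.9942
G0033	0.7726
G0034	-0.402
G0035	0.019
G0036	0.238
G0037	-0.2607
G0038	-0.2662
G0039	-0.8674
G0040	-0.2984
G0041	0.9781
G0042	0.4961
G0043	-0.2175
G0044	0.7538
G0045	0.6578
G0046	-0.1091
G0047	-0.4945
G0048	-0.0618
G0049	-0.7349
G0050	-0.9174
G0051	-0.0473
G0052	-0.9845
G0053	-0.2624
G0054	-0.4923
G0055	0.6112
G0056	-0.2263
G0057	0.2454
G0058	0.5396
G0059	-0.6052
G0060	-0.7241
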