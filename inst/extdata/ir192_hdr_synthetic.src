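#HDRSOURCE 1
#name	ir192_hdr_synthetic
#active_length_cm	0.35999999999999999
#dose_rate_constant	1.1080000000000001
[radial]
r_cm	g
0.25	0.98899999999999999
0.5	0.99399999999999999
0.75	0.998
1	1
1.5	1.0009999999999999
2	1.002
3	1.0029999999999999
4	1.002
5	0.996
6	0.98499999999999999
8	0.95999999999999996
10	0.92000000000000004
[anisotropy]
r_cm	0	10	20	30	40	50	60	70	80	90	100	110	120	130	140	150	160	170	180
0.25	0.65349999999999997	0.77950000000000008	0.874	0.9265000000000001	0.95799999999999996	0.97899999999999998	0.98950000000000005	0.99475000000000002	0.99895	1	0.99895	0.99370000000000003	0.98739999999999994	0.97689999999999999	0.95799999999999996	0.9265000000000001	0.874	0.77950000000000008	0.63250000000000006
0.5	0.66339999999999999	0.78580000000000005	0.87760000000000005	0.92860000000000009	0.95919999999999994	0.97960000000000003	0.98980000000000001	0.99490000000000001	0.99897999999999998	1	0.99897999999999998	0.99387999999999999	0.98775999999999997	0.97755999999999998	0.95919999999999994	0.92860000000000009	0.87760000000000005	0.78580000000000005	0.64300000000000002
1	0.67000000000000004	0.79000000000000004	0.88	0.93000000000000005	0.95999999999999996	0.97999999999999998	0.98999999999999999	0.995	0.999	1	0.999	0.99399999999999999	0.98799999999999999	0.97799999999999998	0.95999999999999996	0.93000000000000005	0.88	0.79000000000000004	0.65000000000000002
2	0.68650000000000011	0.80049999999999999	0.88600000000000001	0.9335	0.96199999999999997	0.98099999999999998	0.99049999999999994	0.99524999999999997	0.99904999999999999	1	0.99904999999999999	0.99429999999999996	0.98860000000000003	0.97909999999999997	0.96199999999999997	0.9335	0.88600000000000001	0.80049999999999999	0.66749999999999998
3	0.69640000000000002	0.80679999999999996	0.88959999999999995	0.93559999999999999	0.96319999999999995	0.98160000000000003	0.99080000000000001	0.99539999999999995	0.99907999999999997	1	0.99907999999999997	0.99448000000000003	0.98895999999999995	0.97975999999999996	0.96319999999999995	0.93559999999999999	0.88959999999999995	0.80679999999999996	0.67799999999999994
5	0.70960000000000001	0.81520000000000004	0.89439999999999997	0.93840000000000001	0.96479999999999999	0.98239999999999994	0.99119999999999997	0.99560000000000004	0.99912000000000001	1	0.99912000000000001	0.99472000000000005	0.98943999999999999	0.98063999999999996	0.96479999999999999	0.93840000000000001	0.89439999999999997	0.81520000000000004	0.69199999999999995
10	0.71950000000000003	0.82150000000000001	0.89800000000000002	0.9405	0.96599999999999997	0.98299999999999998	0.99150000000000005	0.99575000000000002	0.99914999999999998	1	0.99914999999999998	0.99490000000000001	0.98980000000000001	0.98129999999999995	0.96599999999999997	0.9405	0.89800000000000002	0.82150000000000001	0.70250000000000001
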