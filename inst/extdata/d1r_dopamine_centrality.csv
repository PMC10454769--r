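residue,bw,score_no_pam,score_pam,diff,abs_diff
37,TM1.46,0.115,0.132,-0.017,0.017
41,TM1.50,0.118,0.140,-0.022,0.022
62,TM2.42,0.169,0.169,0.000,0.000
63,TM2.43,0.114,0.111,0.003,0.003
65,TM2.45,0.115,0.120,-0.005,0.005
66,TM2.46,0.217,0.204,0.013,0.013
67,TM2.47,0.088,0.100,-0.012,0.012
69,TM2.49,0.162,0.168,-0.006,0.006
70,TM2.50,0.165,0.186,-0.021,0.021
72,TM2.52,0.096,0.105,-0.009,0.009
73,TM2.53,0.137,0.147,-0.010,0.010
77,TM2.57,0.097,0.107,-0.010,0.010
78,TM2.58,0.098,0.108,-0.010,0.010
105,TM3.34,0.093,0.106,-0.013,0.013
106,TM3.35,0.115,0.124,-0.009,0.009
107,TM3.36,0.082,0.083,-0.001,0.001
109,TM3.38,0.116,0.123,-0.007,0.007
110,TM3.39,0.172,0.172,0.000,0.000
111,TM3.40,0.150,0.133,0.017,0.017
113,TM3.42,0.174,0.177,-0.003,0.003
114,TM3.43,0.202,0.167,0.035,0.035
117,TM3.46,0.163,0.146,0.017,0.017
118,TM3.47,0.109,0.086,0.023,0.023
148,TM4.50,0.135,0.144,-0.009,0.009
151,TM4.53,0.094,0.103,-0.009,0.009
203,TM5.47,0.111,0.094,0.017,0.017
206,TM5.50,0.104,0.093,0.011,0.011
210,TM5.54,0.142,0.116,0.026,0.026
214,TM5.58,0.103,0.071,0.032,0.032
281,TM6.44,0.151,0.125,0.026,0.026
285,TM6.48,0.123,0.108,0.015,0.015
321,TM7.43,0.117,0.126,-0.009,0.009
323,TM7.45,0.113,0.090,0.023,0.023
324,TM7.46,0.128,0.142,-0.014,0.014
327,TM7.49,0.154,0.149,0.005,0.005
328,TM7.50,0.090,0.115,-0.025,0.025
331,TM7.53,0.160,0.130,0.030,0.030
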