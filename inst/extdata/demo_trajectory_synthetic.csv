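specimen_id,t,eps_C_ue,eps_T_ue
synthetic_average,0,2819,2807
synthetic_average,0.10000000000000001,2961.8571428571427,2818.2280000000001
synthetic_average,0.20000000000000001,3104.7142857142858,2829.4560000000001
synthetic_average,0.30000000000000004,3223.1666666666665,2840.6840000000002
synthetic_average,0.40000000000000002,3244,2851.9120000000003
synthetic_average,0.5,3264.8333333333335,2863.1399999999999
synthetic_average,0.60000000000000009,3285.6666666666665,2874.3679999999999
synthetic_average,0.70000000000000007,3306.5,2885.596
synthetic_average,0.80000000000000004,3327.3333333333335,2896.8240000000001
synthetic_average,0.90000000000000002,3348.1666666666665,2908.0520000000001
synthetic_average,1,3369,2919.2800000000002
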