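sample_id,rq_qpcr,qpcr_class,ngs_percent,ngs_class,outcome
A1,0.0004047,low_normal,0.05,low_normal,implanted
A2,0.000131,low_normal,0.03,low_normal,implanted
A3,0.001257,low_normal,0.05,low_normal,implanted
A4,0.00103,low_normal,0.04,low_normal,not_implanted
A5,0.00026,low_normal,0.03,low_normal,implanted
A6,0.000406,low_normal,0.03,low_normal,implanted
A7,0.000669,low_normal,0.03,low_normal,not_implanted
A8,0.00151,low_normal,0.04,low_normal,implanted
A9,0.00217,low_normal,0.05,low_normal,implanted
A10,0.001208,low_normal,0.06,low_normal,not_implanted
A11,0.000548,low_normal,0.04,low_normal,not_implanted
A12,0.001932,low_normal,0.04,low_normal,unknown
B1,0.00341,high_abnormal,0.08,high_abnormal,not_implanted
B2,0.0164158,high_abnormal,0.32,high_abnormal,not_implanted
B3,0.00643,high_abnormal,0.20,high_abnormal,not_implanted
B4,0.000602,low_normal,0.04,low_normal,unknown
B5,0.01075,high_abnormal,0.11,high_abnormal,not_implanted
B6,0.00222,low_normal,0.06,low_normal,not_implanted
B7,0.0033,high_abnormal,0.11,high_abnormal,not_implanted
B8,0.00426,high_abnormal,0.13,high_abnormal,not_implanted
B9,0.00412,high_abnormal,0.16,high_abnormal,not_implanted
B10,0.0060,high_abnormal,0.09,high_abnormal,not_implanted
B11,0.0069,high_abnormal,0.08,high_abnormal,not_implanted
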