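species,sex,temperature_C,mean_dev_time_days,se_days,n
C. cunea,female,10,,,50
C. cunea,female,15,115,0,50
C. cunea,female,20,48.8,0.3,50
C. cunea,female,25,23.13,0.04,50
C. cunea,female,30,21.50,0.02,50
C. cunea,male,10,,,50
C. cunea,male,15,115,0,50
C. cunea,male,20,48,2,50
C. cunea,male,25,23.1,0.3,50
C. cunea,male,30,21.6,0.1,50
P. omnivorus,female,10,,,50
P. omnivorus,female,15,,,50
P. omnivorus,female,20,19.76,0.06,50
P. omnivorus,female,25,19.98,0.04,50
P. omnivorus,female,30,22.1,0.1,50
P. omnivorus,male,10,,,50
P. omnivorus,male,15,,,50
P. omnivorus,male,20,19.77,0.02,50
P. omnivorus,male,25,20.08,0.02,50
P. omnivorus,male,30,22.06,0.05,50
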