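id,duration_slots,deadline_days,waited_days
P001,4,30,21
P002,8,60,10
P003,2,360,40
P004,6,90,75
P005,3,180,12
P006,10,60,2
P007,4,30,25
P008,2,90,0
P009,6,360,100
P010,8,180,30
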