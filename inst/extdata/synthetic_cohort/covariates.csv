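subject_id,group,age,sex,icv,comorbid_adhd,comorbid_t2d,qc_rating
sub0001,HC,32.88536177063361,1,1552063.0720104866,0,1,2
sub0002,HC,58.282976193353534,0,1531007.9302411266,1,0,2
sub0003,HC,36.77658567158505,1,1418947.884032828,0,0,1
sub0004,SZ,41.18931542756036,1,1460671.4814006821,1,0,1
sub0005,SZ,21.56061936635524,1,1458726.2958283136,0,0,1
sub0006,SZ,34.73245178628713,1,1514926.782169905,0,1,1
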