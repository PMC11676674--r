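condition,replicate,N1,N2,N3,n_bi_with_mn
NC,1,590,410,18,4
NC,2,602,401,15,5
NC,3,585,415,20,4
MMC-0.025,1,611,369,20,21
MMC-0.025,2,620,360,17,20
MMC-0.025,3,605,372,19,22
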