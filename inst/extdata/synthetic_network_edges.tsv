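from	to	length_km
site01	site02	2.43
site02	site03	3.12
site03	site04	5.457
site02	site05	3.563
site03	site06	4.588
site01	site07	4.603
site02	site08	3.916
site07	site09	7.584
site05	site10	3.105
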