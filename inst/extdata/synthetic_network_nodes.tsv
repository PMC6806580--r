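node	longitude	latitude
site01	116.5	25.2
site02	116.48808	25.2152
site03	116.51333	25.20839
site04	116.49781	25.16889
site05	116.51119	25.19767
site06	116.52973	25.24034
site07	116.4733	25.1743
site08	116.52106	25.21323
site09	116.51702	25.21687
site10	116.49847	25.21854
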