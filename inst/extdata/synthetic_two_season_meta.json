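[{"sample_id":"wet_site01","season":"wet","site":"site01","longitude":116.5,"latitude":25.2},{"sample_id":"wet_site02","season":"wet","site":"site02","longitude":116.48808,"latitude":25.2152},{"sample_id":"wet_site03","season":"wet","site":"site03","longitude":116.51333,"latitude":25.20839},{"sample_id":"wet_site04","season":"wet","site":"site04","longitude":116.49781,"latitude":25.16889},{"sample_id":"wet_site05","season":"wet","site":"site05","longitude":116.51119,"latitude":25.19767},{"sample_id":"wet_site06","season":"wet","site":"site06","longitude":116.52973,"latitude":25.24034},{"sample_id":"wet_site07","season":"wet","site":"site07","longitude":116.4733,"latitude":25.1743},{"sample_id":"wet_site08","season":"wet","site":"site08","longitude":116.52106,"latitude":25.21323},{"sample_id":"wet_site09","season":"wet","site":"site09","longitude":116.51702,"latitude":25.21687},{"sample_id":"wet_site10","season":"wet","site":"site10","longitude":116.49847,"latitude":25.21854},{"sample_id":"dry_site01","season":"dry","site":"site01","longitude":116.5,"latitude":25.2},{"sample_id":"dry_site02","season":"dry","site":"site02","longitude":116.48808,"latitude":25.2152},{"sample_id":"dry_site03","season":"dry","site":"site03","longitude":116.51333,"latitude":25.20839},{"sample_id":"dry_site04","season":"dry","site":"site04","longitude":116.49781,"latitude":25.16889},{"sample_id":"dry_site05","season":"dry","site":"site05","longitude":116.51119,"latitude":25.19767},{"sample_id":"dry_site06","season":"dry","site":"site06","longitude":116.52973,"latitude":25.24034},{"sample_id":"dry_site07","season":"dry","site":"site07","longitude":116.4733,"latitude":25.1743},{"sample_id":"dry_site08","season":"dry","site":"site08","longitude":116.52106,"latitude":25.21323},{"sample_id":"dry_site09","season":"dry","site":"site09","longitude":116.51702,"latitude":25.21687},{"sample_id":"dry_site10","season":"dry","site":"site10","longitude":116.49847,"latitude":25.21854}]
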