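# Default resistome search terms: stress/resistance function families
# reported for radiation- and desiccation-tolerant bacteria.
# One case-insensitive substring per line; edit or replace freely.
stress
resist
efflux
permease
transporter
antimicrobial
heat shock
shock
repair
radiat
oxidative
peroxid
glutathione
detox
osmo
chaperone
betaine
siderophore
multidrug
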