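region	fraction
pulmonary	0.086310
tracheobronchial	0.057143
gastrointestinal	0.423810
head	0.317857
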