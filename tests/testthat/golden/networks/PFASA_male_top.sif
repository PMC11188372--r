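TF01	regulates	Gene00001
TF01	regulates	Gene00002
TF01	regulates	Gene00003
TF01	regulates	Gene00004
TF01	regulates	Gene00005
TF02	regulates	Gene00006
TF02	regulates	Gene00007
TF02	regulates	Gene00008
TF02	regulates	Gene00009
TF03	regulates	Gene00010
TF03	regulates	Gene00011
TF03	regulates	Gene00012
TF03	regulates	Gene00013
TF03	regulates	Gene00014
TF03	regulates	Gene00015
TF03	regulates	Gene00016
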