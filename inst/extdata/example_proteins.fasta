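>syn_00001
WVPMWAFCLKPSYCCWLMLMMHQGSQVFALPYVFKFYLAWFFDFPAGDDDAHYNCAHHKYGYPS
>syn_00002
DRMCKRMMCNLSDPPFHECSKVSCIDTFRDSGCRAGQQESECKA
>syn_00003
SYYESPQPLESMLRKIQKGAGTNAAGESHCQDNCFQAHFLLQEYCAIQKFGVKFKEQIMGIWLKEFCE
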