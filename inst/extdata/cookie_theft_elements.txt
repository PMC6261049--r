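boy
girl
woman
cookie
jar
stool
sink
water
plate
dishcloth
cupboard
curtain
window
counter
kitchen
overflowing
taking_cookie
stool_wobbling
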