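Um, there is a mother washing dishes in the kitchen and the, the water is
falling over the side. Uh the boy is reaching- reaching up into the cookie
jar and the chair is um falling over. The girl is reaching for a cookie
&uh and the mother did not see anything.
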