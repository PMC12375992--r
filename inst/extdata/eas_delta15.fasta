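>EAS_delta15 class I hydrophobin EAS loop-deletion variant, Neurospora crassa
SATTIGPNTCSIDDYKPYCCQSMSGSASLGCVVGVIGSQCGASVKCCKDDVTNTGNSFLI
INAANCVA
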