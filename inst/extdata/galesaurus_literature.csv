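specimen_id,taxon,bsl_mm,stage,max_l,max_r,mand_l,mand_r,source
TM 83,galesaurus,,,12,?,–,–,literature
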