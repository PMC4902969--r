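(archosaur:1,(hokou_gecko:1,(sand_lizard:1,(japanese_four_striped_snake:1,(water_monitor:1,(butterfly_lizard:1,(anole:1,dragon:1)Agamid_Anole:1)Iguania:1)Anguimorpha_Iguania:1)Toxicofera:1)Lacertoidea_Toxicofera:1)Squamata:1)Amniote_root;
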