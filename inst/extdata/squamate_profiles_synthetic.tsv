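species_id	chromosome_id	segment
archosaur	c01	GGA1p
archosaur	c02	GGA1q
archosaur	c03	GGA2p
archosaur	c04	GGA2q
archosaur	c05	GGA3
archosaur	c06	GGA4qa
archosaur	c06	GGA4qb
archosaur	c07	GGA5
archosaur	c08	GGA6
archosaur	c09	GGA7
archosaur	c10	GGA8
archosaur	c11	GGA9
archosaur	m01	GGA13a
archosaur	m01	GGA13b
archosaur	m01	GGA13c
archosaur	m02	GGA27
hokou_gecko	c01	GGA1p
hokou_gecko	c02	GGA1q
hokou_gecko	c02	GGA13a
hokou_gecko	c03	GGA2p
hokou_gecko	c04	GGA2q
hokou_gecko	c05	GGA3
hokou_gecko	c06	GGA4qa
hokou_gecko	c06	GGA4qb
hokou_gecko	c07	GGA5
hokou_gecko	c07	GGA13b
hokou_gecko	c08	GGA6
hokou_gecko	c08	GGA9
hokou_gecko	c09	GGA7
hokou_gecko	c09	GGA13c
hokou_gecko	c10	GGA8
hokou_gecko	m01	GGA27
sand_lizard	c01	GGA1p
sand_lizard	c02	GGA1q
sand_lizard	c02	GGA13a
sand_lizard	c03	GGA2p
sand_lizard	c04	GGA2q
sand_lizard	c05	GGA3
sand_lizard	c06	GGA4qa
sand_lizard	c06	GGA4qb
sand_lizard	c07	GGA5
sand_lizard	c07	GGA13b
sand_lizard	c08	GGA6
sand_lizard	c08	GGA9
sand_lizard	c09	GGA7
sand_lizard	c09	GGA13c
sand_lizard	c10	GGA8
sand_lizard	m01	GGA27
japanese_four_striped_snake	c01	GGA1q
japanese_four_striped_snake	c01	GGA13a
japanese_four_striped_snake	c02	GGA2p
japanese_four_striped_snake	c02	GGA27
japanese_four_striped_snake	c03	GGA2q
japanese_four_striped_snake	c03	GGA3
japanese_four_striped_snake	c04	GGA5
japanese_four_striped_snake	c04	GGA13b
japanese_four_striped_snake	c04	GGA8
japanese_four_striped_snake	c05	GGA6
japanese_four_striped_snake	c05	GGA9
japanese_four_striped_snake	c06	GGA1p
japanese_four_striped_snake	c06	GGA4qa
japanese_four_striped_snake	c07	GGA4qb
japanese_four_striped_snake	c08	GGA7
japanese_four_striped_snake	c08	GGA13c
water_monitor	c01	GGA1p
water_monitor	c01	GGA4qa
water_monitor	c01	GGA4qb
water_monitor	c02	GGA1q
water_monitor	c02	GGA13a
water_monitor	c03	GGA2p
water_monitor	c03	GGA27
water_monitor	c04	GGA2q
water_monitor	c04	GGA3
water_monitor	c05	GGA5
water_monitor	c05	GGA13b
water_monitor	c05	GGA8
water_monitor	c06	GGA6
water_monitor	c06	GGA9
water_monitor	c07	GGA7
water_monitor	c07	GGA13c
butterfly_lizard	c01	GGA1p
butterfly_lizard	c01	GGA4qa
butterfly_lizard	c01	GGA4qb
butterfly_lizard	c02	GGA1q
butterfly_lizard	c02	GGA6
butterfly_lizard	c02	GGA9
butterfly_lizard	c03	GGA2p
butterfly_lizard	c03	GGA27
butterfly_lizard	c04	GGA2q
butterfly_lizard	c04	GGA3
butterfly_lizard	c05	GGA5
butterfly_lizard	c05	GGA13b
butterfly_lizard	c05	GGA8
butterfly_lizard	c06	GGA7
butterfly_lizard	c06	GGA13c
anole	c01	GGA1p
anole	c01	GGA4qa
anole	c01	GGA4qb
anole	c02	GGA1q
anole	c02	GGA13a
anole	c02	GGA6
anole	c02	GGA9
anole	c03	GGA2p
anole	c03	GGA27
anole	c04	GGA2q
anole	c04	GGA3
anole	c05	GGA5
anole	c05	GGA13b
anole	c05	GGA8
anole	c06	GGA7
anole	c06	GGA13c
dragon	c01	GGA1p
dragon	c01	GGA4qa
dragon	c01	GGA4qb
dragon	c02	GGA1q
dragon	c02	GGA6
dragon	c02	GGA9
dragon	c03	GGA2p
dragon	c03	GGA27
dragon	c04	GGA2q
dragon	c04	GGA3
dragon	c05	GGA5
dragon	c05	GGA13b
dragon	c05	GGA8
dragon	c06	GGA7
dragon	c06	GGA13c
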