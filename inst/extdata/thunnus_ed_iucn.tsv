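species	common_name	ed_my	iucn_category
Thunnus_alalunga	Albacore tuna	12.2	NT
Thunnus_albacares	Yellowfin tuna	9.0	NT
Thunnus_atlanticus	Blackfin tuna	8.8	LC
Thunnus_maccoyii	Southern bluefin tuna	9.6	CR
Thunnus_obesus	Bigeye tuna	9.0	VU
Thunnus_orientalis	Pacific bluefin tuna	8.1	VU
Thunnus_thynnus	Atlantic bluefin tuna	8.1	EN
Thunnus_tonggol	Longtail tuna	8.8	DD
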