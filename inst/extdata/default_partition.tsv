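roi_label	network
MTL_01	MTL
MTL_02	MTL
MTL_03	MTL
MTL_04	MTL
MTL_05	MTL
MTL_06	MTL
DM_01	DM
DM_02	DM
DM_03	DM
DM_04	DM
DM_05	DM
DM_06	DM
DM_07	DM
DM_08	DM
DM_09	DM
Core_01	Core
Core_02	Core
Core_03	Core
Core_04	Core
Core_05	Core
Core_06	Core
Core_07	Core
Core_08	Core
Core_09	Core
FPCNA_01	FPCNA
FPCNA_02	FPCNA
FPCNA_03	FPCNA
FPCNA_04	FPCNA
FPCNA_05	FPCNA
FPCNA_06	FPCNA
FPCNA_07	FPCNA
FPCNA_08	FPCNA
FPCNA_09	FPCNA
FPCNA_10	FPCNA
FPCNA_11	FPCNA
FPCNB_01	FPCNB
FPCNB_02	FPCNB
FPCNB_03	FPCNB
FPCNB_04	FPCNB
FPCNB_05	FPCNB
FPCNB_06	FPCNB
FPCNB_07	FPCNB
FPCNB_08	FPCNB
FPCNB_09	FPCNB
DAN_01	DAN
DAN_02	DAN
DAN_03	DAN
DAN_04	DAN
DAN_05	DAN
DAN_06	DAN
DAN_07	DAN
DAN_08	DAN
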