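where	kind	name	dtype
/	attr	CREATED_BY_LIBRARY_VERSION	
/	attr	FILE_FORMAT_MAJOR_VERSION	
/	attr	FILE_FORMAT_MINOR_VERSION	
/	attr	IMSType	
/	attr	metadataXML	
ms1	attr	IMSAlpha	
ms1	attr	IMSBeta	
ms1	attr	IMSGamma	
ms1	attr	firstScanRetentionTimeOffset	
ms1	attr	precursorCenter	
ms1	attr	precursorLower	
ms1	attr	precursorUpper	
ms1	attr	scanCycleTime	
ms1	dataset	IMSAlphaPerScan	H5T_IEEE_F64LE
ms1	dataset	IMSBetaPerScan	H5T_IEEE_F64LE
ms1	dataset	imsCoord	H5T_STD_U32LE
ms1	dataset	intensity	H5T_STD_U32LE
ms1	dataset	retentionTimeIdx	H5T_STD_U32LE
ms2-001	attr	IMSAlpha	
ms2-001	attr	IMSBeta	
ms2-001	attr	IMSGamma	
ms2-001	attr	firstScanRetentionTimeOffset	
ms2-001	attr	precursorCenter	
ms2-001	attr	precursorLower	
ms2-001	attr	precursorUpper	
ms2-001	attr	scanCycleTime	
ms2-001	dataset	IMSAlphaPerScan	H5T_IEEE_F64LE
ms2-001	dataset	IMSBetaPerScan	H5T_IEEE_F64LE
ms2-001	dataset	imsCoord	H5T_STD_U32LE
ms2-001	dataset	intensity	H5T_STD_U32LE
ms2-001	dataset	retentionTimeIdx	H5T_STD_U32LE
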