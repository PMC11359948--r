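OCT_FULL_LBP1
OCT_FULL_LBP2
OCT_FULL_LBP3
OCT_FULL_LBP4
OCT_FULL_LBP5
OCT_FULL_LBP6
OCT_FULL_LBP7
OCT_FULL_LBP8
OCT_FULL_LBP9
OCT_FULL_LBP10
OCT_FULL_LBP11
OCT_FULL_LBP12
OCT_FULL_LBP13
OCT_FULL_LBP14
OCT_FULL_LBP15
OCT_FULL_LBP16
OCT_FULL_LBP17
OCT_FULL_LBP18
OCT_FULL_LBP19
OCT_FULL_LBP20
OCT_FULL_LBP21
OCT_FULL_LBP22
OCT_FULL_LBP23
OCT_FULL_LBP24
OCT_FULL_LBP25
OCT_FULL_LBP26
OCT_FULL_LBP27
OCT_FULL_LBP28
OCT_FULL_LBP29
OCT_FULL_LBP30
OCT_FULL_LBP31
OCT_FULL_LBP32
OCT_FULL_LBP33
OCT_FULL_LBP34
OCT_FULL_LBP35
OCT_FULL_LBP36
OCT_FULL_LBP37
OCT_FULL_LBP38
OCT_FULL_LBP39
OCT_FULL_LBP40
OCT_FULL_LBP41
OCT_FULL_LBP42
OCT_FULL_LBP43
OCT_FULL_LBP44
OCT_FULL_LBP45
OCT_FULL_LBP46
OCT_FULL_LBP47
OCT_FULL_LBP48
OCT_FULL_LBP49
OCT_FULL_LBP50
OCT_FULL_LBP51
OCT_FULL_LBP52
OCT_FULL_LBP53
OCT_FULL_LBP54
OCT_FULL_LBP55
OCT_FULL_LBP56
OCT_FULL_LBP57
OCT_FULL_LBP58
OCT_FULL_LBP59
OCT_ILM-OPL_LBP1
OCT_ILM-OPL_LBP2
OCT_ILM-OPL_LBP3
OCT_ILM-OPL_LBP4
OCT_ILM-OPL_LBP5
OCT_ILM-OPL_LBP6
OCT_ILM-OPL_LBP7
OCT_ILM-OPL_LBP8
OCT_ILM-OPL_LBP9
OCT_ILM-OPL_LBP10
OCT_ILM-OPL_LBP11
OCT_ILM-OPL_LBP12
OCT_ILM-OPL_LBP13
OCT_ILM-OPL_LBP14
OCT_ILM-OPL_LBP15
OCT_ILM-OPL_LBP16
OCT_ILM-OPL_LBP17
OCT_ILM-OPL_LBP18
OCT_ILM-OPL_LBP19
OCT_ILM-OPL_LBP20
OCT_ILM-OPL_LBP21
OCT_ILM-OPL_LBP22
OCT_ILM-OPL_LBP23
OCT_ILM-OPL_LBP24
OCT_ILM-OPL_LBP25
OCT_ILM-OPL_LBP26
OCT_ILM-OPL_LBP27
OCT_ILM-OPL_LBP28
OCT_ILM-OPL_LBP29
OCT_ILM-OPL_LBP30
OCT_ILM-OPL_LBP31
OCT_ILM-OPL_LBP32
OCT_ILM-OPL_LBP33
OCT_ILM-OPL_LBP34
OCT_ILM-OPL_LBP35
OCT_ILM-OPL_LBP36
OCT_ILM-OPL_LBP37
OCT_ILM-OPL_LBP38
OCT_ILM-OPL_LBP39
OCT_ILM-OPL_LBP40
OCT_ILM-OPL_LBP41
OCT_ILM-OPL_LBP42
OCT_ILM-OPL_LBP43
OCT_ILM-OPL_LBP44
OCT_ILM-OPL_LBP45
OCT_ILM-OPL_LBP46
OCT_ILM-OPL_LBP47
OCT_ILM-OPL_LBP48
OCT_ILM-OPL_LBP49
OCT_ILM-OPL_LBP50
OCT_ILM-OPL_LBP51
OCT_ILM-OPL_LBP52
OCT_ILM-OPL_LBP53
OCT_ILM-OPL_LBP54
OCT_ILM-OPL_LBP55
OCT_ILM-OPL_LBP56
OCT_ILM-OPL_LBP57
OCT_ILM-OPL_LBP58
OCT_ILM-OPL_LBP59
OCT_OPL-BM_LBP1
OCT_OPL-BM_LBP2
OCT_OPL-BM_LBP3
OCT_OPL-BM_LBP4
OCT_OPL-BM_LBP5
OCT_OPL-BM_LBP6
OCT_OPL-BM_LBP7
OCT_OPL-BM_LBP8
OCT_OPL-BM_LBP9
OCT_OPL-BM_LBP10
OCT_OPL-BM_LBP11
OCT_OPL-BM_LBP12
OCT_OPL-BM_LBP13
OCT_OPL-BM_LBP14
OCT_OPL-BM_LBP15
OCT_OPL-BM_LBP16
OCT_OPL-BM_LBP17
OCT_OPL-BM_LBP18
OCT_OPL-BM_LBP19
OCT_OPL-BM_LBP20
OCT_OPL-BM_LBP21
OCT_OPL-BM_LBP22
OCT_OPL-BM_LBP23
OCT_OPL-BM_LBP24
OCT_OPL-BM_LBP25
OCT_OPL-BM_LBP26
OCT_OPL-BM_LBP27
OCT_OPL-BM_LBP28
OCT_OPL-BM_LBP29
OCT_OPL-BM_LBP30
OCT_OPL-BM_LBP31
OCT_OPL-BM_LBP32
OCT_OPL-BM_LBP33
OCT_OPL-BM_LBP34
OCT_OPL-BM_LBP35
OCT_OPL-BM_LBP36
OCT_OPL-BM_LBP37
OCT_OPL-BM_LBP38
OCT_OPL-BM_LBP39
OCT_OPL-BM_LBP40
OCT_OPL-BM_LBP41
OCT_OPL-BM_LBP42
OCT_OPL-BM_LBP43
OCT_OPL-BM_LBP44
OCT_OPL-BM_LBP45
OCT_OPL-BM_LBP46
OCT_OPL-BM_LBP47
OCT_OPL-BM_LBP48
OCT_OPL-BM_LBP49
OCT_OPL-BM_LBP50
OCT_OPL-BM_LBP51
OCT_OPL-BM_LBP52
OCT_OPL-BM_LBP53
OCT_OPL-BM_LBP54
OCT_OPL-BM_LBP55
OCT_OPL-BM_LBP56
OCT_OPL-BM_LBP57
OCT_OPL-BM_LBP58
OCT_OPL-BM_LBP59
OCTA_FULL_LBP1
OCTA_FULL_LBP2
OCTA_FULL_LBP3
OCTA_FULL_LBP4
OCTA_FULL_LBP5
OCTA_FULL_LBP6
OCTA_FULL_LBP7
OCTA_FULL_LBP8
OCTA_FULL_LBP9
OCTA_FULL_LBP10
OCTA_FULL_LBP11
OCTA_FULL_LBP12
OCTA_FULL_LBP13
OCTA_FULL_LBP14
OCTA_FULL_LBP15
OCTA_FULL_LBP16
OCTA_FULL_LBP17
OCTA_FULL_LBP18
OCTA_FULL_LBP19
OCTA_FULL_LBP20
OCTA_FULL_LBP21
OCTA_FULL_LBP22
OCTA_FULL_LBP23
OCTA_FULL_LBP24
OCTA_FULL_LBP25
OCTA_FULL_LBP26
OCTA_FULL_LBP27
OCTA_FULL_LBP28
OCTA_FULL_LBP29
OCTA_FULL_LBP30
OCTA_FULL_LBP31
OCTA_FULL_LBP32
OCTA_FULL_LBP33
OCTA_FULL_LBP34
OCTA_FULL_LBP35
OCTA_FULL_LBP36
OCTA_FULL_LBP37
OCTA_FULL_LBP38
OCTA_FULL_LBP39
OCTA_FULL_LBP40
OCTA_FULL_LBP41
OCTA_FULL_LBP42
OCTA_FULL_LBP43
OCTA_FULL_LBP44
OCTA_FULL_LBP45
OCTA_FULL_LBP46
OCTA_FULL_LBP47
OCTA_FULL_LBP48
OCTA_FULL_LBP49
OCTA_FULL_LBP50
OCTA_FULL_LBP51
OCTA_FULL_LBP52
OCTA_FULL_LBP53
OCTA_FULL_LBP54
OCTA_FULL_LBP55
OCTA_FULL_LBP56
OCTA_FULL_LBP57
OCTA_FULL_LBP58
OCTA_FULL_LBP59
OCTA_ILM-OPL_LBP1
OCTA_ILM-OPL_LBP2
OCTA_ILM-OPL_LBP3
OCTA_ILM-OPL_LBP4
OCTA_ILM-OPL_LBP5
OCTA_ILM-OPL_LBP6
OCTA_ILM-OPL_LBP7
OCTA_ILM-OPL_LBP8
OCTA_ILM-OPL_LBP9
OCTA_ILM-OPL_LBP10
OCTA_ILM-OPL_LBP11
OCTA_ILM-OPL_LBP12
OCTA_ILM-OPL_LBP13
OCTA_ILM-OPL_LBP14
OCTA_ILM-OPL_LBP15
OCTA_ILM-OPL_LBP16
OCTA_ILM-OPL_LBP17
OCTA_ILM-OPL_LBP18
OCTA_ILM-OPL_LBP19
OCTA_ILM-OPL_LBP20
OCTA_ILM-OPL_LBP21
OCTA_ILM-OPL_LBP22
OCTA_ILM-OPL_LBP23
OCTA_ILM-OPL_LBP24
OCTA_ILM-OPL_LBP25
OCTA_ILM-OPL_LBP26
OCTA_ILM-OPL_LBP27
OCTA_ILM-OPL_LBP28
OCTA_ILM-OPL_LBP29
OCTA_ILM-OPL_LBP30
OCTA_ILM-OPL_LBP31
OCTA_ILM-OPL_LBP32
OCTA_ILM-OPL_LBP33
OCTA_ILM-OPL_LBP34
OCTA_ILM-OPL_LBP35
OCTA_ILM-OPL_LBP36
OCTA_ILM-OPL_LBP37
OCTA_ILM-OPL_LBP38
OCTA_ILM-OPL_LBP39
OCTA_ILM-OPL_LBP40
OCTA_ILM-OPL_LBP41
OCTA_ILM-OPL_LBP42
OCTA_ILM-OPL_LBP43
OCTA_ILM-OPL_LBP44
OCTA_ILM-OPL_LBP45
OCTA_ILM-OPL_LBP46
OCTA_ILM-OPL_LBP47
OCTA_ILM-OPL_LBP48
OCTA_ILM-OPL_LBP49
OCTA_ILM-OPL_LBP50
OCTA_ILM-OPL_LBP51
OCTA_ILM-OPL_LBP52
OCTA_ILM-OPL_LBP53
OCTA_ILM-OPL_LBP54
OCTA_ILM-OPL_LBP55
OCTA_ILM-OPL_LBP56
OCTA_ILM-OPL_LBP57
OCTA_ILM-OPL_LBP58
OCTA_ILM-OPL_LBP59
OCTA_OPL-BM_LBP1
OCTA_OPL-BM_LBP2
OCTA_OPL-BM_LBP3
OCTA_OPL-BM_LBP4
OCTA_OPL-BM_LBP5
OCTA_OPL-BM_LBP6
OCTA_OPL-BM_LBP7
OCTA_OPL-BM_LBP8
OCTA_OPL-BM_LBP9
OCTA_OPL-BM_LBP10
OCTA_OPL-BM_LBP11
OCTA_OPL-BM_LBP12
OCTA_OPL-BM_LBP13
OCTA_OPL-BM_LBP14
OCTA_OPL-BM_LBP15
OCTA_OPL-BM_LBP16
OCTA_OPL-BM_LBP17
OCTA_OPL-BM_LBP18
OCTA_OPL-BM_LBP19
OCTA_OPL-BM_LBP20
OCTA_OPL-BM_LBP21
OCTA_OPL-BM_LBP22
OCTA_OPL-BM_LBP23
OCTA_OPL-BM_LBP24
OCTA_OPL-BM_LBP25
OCTA_OPL-BM_LBP26
OCTA_OPL-BM_LBP27
OCTA_OPL-BM_LBP28
OCTA_OPL-BM_LBP29
OCTA_OPL-BM_LBP30
OCTA_OPL-BM_LBP31
OCTA_OPL-BM_LBP32
OCTA_OPL-BM_LBP33
OCTA_OPL-BM_LBP34
OCTA_OPL-BM_LBP35
OCTA_OPL-BM_LBP36
OCTA_OPL-BM_LBP37
OCTA_OPL-BM_LBP38
OCTA_OPL-BM_LBP39
OCTA_OPL-BM_LBP40
OCTA_OPL-BM_LBP41
OCTA_OPL-BM_LBP42
OCTA_OPL-BM_LBP43
OCTA_OPL-BM_LBP44
OCTA_OPL-BM_LBP45
OCTA_OPL-BM_LBP46
OCTA_OPL-BM_LBP47
OCTA_OPL-BM_LBP48
OCTA_OPL-BM_LBP49
OCTA_OPL-BM_LBP50
OCTA_OPL-BM_LBP51
OCTA_OPL-BM_LBP52
OCTA_OPL-BM_LBP53
OCTA_OPL-BM_LBP54
OCTA_OPL-BM_LBP55
OCTA_OPL-BM_LBP56
OCTA_OPL-BM_LBP57
OCTA_OPL-BM_LBP58
OCTA_OPL-BM_LBP59
capillary_VAD_max
capillary_VAD_mean
capillary_VAD_median
capillary_VAD_std
capillary_VAD_skew
capillary_VAD_kur
capillary_VSD_max
capillary_VSD_mean
capillary_VSD_median
capillary_VSD_std
capillary_VSD_skew
capillary_VSD_kur
capillary_VPI_max
capillary_VPI_mean
capillary_VPI_median
capillary_VPI_std
capillary_VPI_skew
capillary_VPI_kur
capillary_VDI_max
capillary_VDI_mean
capillary_VDI_median
capillary_VDI_std
capillary_VDI_skew
capillary_VDI_kur
capillary_VCI_max
capillary_VCI_mean
capillary_VCI_median
capillary_VCI_std
capillary_VCI_skew
capillary_VCI_kur
capillary_VCP_max
capillary_VCP_mean
capillary_VCP_median
capillary_VCP_std
capillary_VCP_skew
capillary_VCP_kur
capillary_SP_max
capillary_SP_mean
capillary_SP_median
capillary_SP_std
capillary_SP_skew
capillary_SP_kur
capillary_FD
large_vessel_VAD_max
large_vessel_VAD_mean
large_vessel_VAD_median
large_vessel_VAD_std
large_vessel_VAD_skew
large_vessel_VAD_kur
large_vessel_VSD_max
large_vessel_VSD_mean
large_vessel_VSD_median
large_vessel_VSD_std
large_vessel_VSD_skew
large_vessel_VSD_kur
large_vessel_VPI_max
large_vessel_VPI_mean
large_vessel_VPI_median
large_vessel_VPI_std
large_vessel_VPI_skew
large_vessel_VPI_kur
large_vessel_VDI_max
large_vessel_VDI_mean
large_vessel_VDI_median
large_vessel_VDI_std
large_vessel_VDI_skew
large_vessel_VDI_kur
large_vessel_VCI_max
large_vessel_VCI_mean
large_vessel_VCI_median
large_vessel_VCI_std
large_vessel_VCI_skew
large_vessel_VCI_kur
large_vessel_VCP_max
large_vessel_VCP_mean
large_vessel_VCP_median
large_vessel_VCP_std
large_vessel_VCP_skew
large_vessel_VCP_kur
large_vessel_SP_max
large_vessel_SP_mean
large_vessel_SP_median
large_vessel_SP_std
large_vessel_SP_skew
large_vessel_SP_kur
large_vessel_FD
FAZ_area
FAZ_perimeter
FAZ_CI
FAZ_diameter
FAZ_centroid_x
FAZ_centroid_y
FAZ_eccentricity
FAZ_compactness
FAZ_flatness
FAZ_anisotropy
FAZ_convexity
FAZ_angle
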