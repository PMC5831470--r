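# Published putative mature peptides of three parasitoid wasps
# (N. vitripennis, F. arisanus, A. armilla) in shorthand notation:
# trailing "a" = amide, leading "pQ" = pyroglutamate, leading "..." = partial.
# The NPLP1 A. armilla entry printed as "aNIAALARDYSLPS" in the source is
# encoded here as NIAALARDYSLPSa (irregular leading "a" read as a
# typeset slip for the trailing amide).
species	family	notation
N_vitripennis	ACP	pQVTFSKGWGPa
N_vitripennis	AKH	pQLNFSTGWa
N_vitripennis	AST-A	LPIYQFGLa
N_vitripennis	AST-A	SQPFSFGLa
N_vitripennis	AST-A	TRPYSFGLa
N_vitripennis	AST-A	TGGFNFGLa
N_vitripennis	AST-A	DKYLFGLa
N_vitripennis	AST-CC	GQAKGRVYWRCYFNAVTCF
N_vitripennis	AST-CCC	NYWRQCAFNAVSCF
N_vitripennis	AT	GFQPEYISTAYGFa
N_vitripennis	AVLP	CLITNCPRGa
N_vitripennis	CCAP	PFCNAFTGCa
N_vitripennis	CCHa-1	SCLSYGHSCWGAHa
N_vitripennis	CCHa-2	GCSAFGHSCYGGHa
N_vitripennis	CNMa	TSYMALCHFKICNMa
N_vitripennis	CRZ	pQTFQYSRGWTNa
N_vitripennis	DH31	GLDLGLNRGFSGSQAAKHLMGLAAANYAGGPa
N_vitripennis	DH44	IGSLSVVNSVDVLRERVLLELARRKAMENQQQLGENQYVFKSVa
N_vitripennis	ETH	DEPPAFFLKIAKNIPRIa
N_vitripennis	FMRFa	SSSSGGNLGSSFIRYa
N_vitripennis	FMRFa	SDVIIRYa
N_vitripennis	ITG	ITGKNNRLY
N_vitripennis	MS	pQDVDHVFLRFa
N_vitripennis	NPF	EPEPMARPTRPKVFESPEELRQYLDLVKEYYSLSGKARYa
N_vitripennis	OK-A	NFDEIDRSGFSGFS
N_vitripennis	OK-A	NFDEIDRSGFSGFN
N_vitripennis	OK-A	NFDEIDRTGFSGFN
N_vitripennis	OK-A	NFDEIDRSGVPGFA
N_vitripennis	PDF	NSELINSLLSLPKNMNNAa
N_vitripennis	PK	QETTFTPRLa
N_vitripennis	PK	DQQAPPPMFPPRLa
N_vitripennis	trypto-PK	QYDGRGSDMVEGPRVERMHPETSGGCVGAHCLTQNSEGPVGAMWFGPRLa
N_vitripennis	RYa	pQDNFYASGRFa
N_vitripennis	RYa	SEDRSAGNSLKDSSLFSSARFa
N_vitripennis	RYa	SEDRNTGNSLRDSSSFFPARYa
N_vitripennis	RYa	SEDRSTGNSLRDSSSFFPARFa
N_vitripennis	RYa	SEDRSTGNSLKDSSSFSPARYa
N_vitripennis	RYa	SEDRSSGNSLKESSFFSPGRYa
N_vitripennis	RYa	SEGHKNPKELPKFFEIKPRVDQFFIGSRYa
N_vitripennis	SIFa	AYRKPPFNGSIFa
N_vitripennis	sNPF	AAERSPSLRLRFa
N_vitripennis	sNPF	SYPKYPRSPSLRLRFa
N_vitripennis	TK	ASMRGFQGMRa
N_vitripennis	TK	APMGFQGMRa
N_vitripennis	TK	AMMGGFQGMRa
N_vitripennis	TK	ALLGFHGMRa
N_vitripennis	TK	PMMMGFHGMRa
N_vitripennis	TK	SPYRFFGTRa
N_vitripennis	TK	FVGVRa
F_arisanus	AKH	pQLTFSTGWa
F_arisanus	AST-A	FPDYLYSFGIa
F_arisanus	AST-A	NSPYSFGVa
F_arisanus	AST-A	NSPSHAYGFGIa
F_arisanus	AST-CC	GPVNGSVYWRCYFNAVTCF
F_arisanus	AST-CCC	TYWKQCAFNAVSCF
F_arisanus	AT	GIRPGSLQTARDFa
F_arisanus	AVLP	CLITNCPRGa
F_arisanus	CCAP	PFCNAFTGCa
F_arisanus	CNMa	TSYMGLCHFKICNMa
F_arisanus	CRZ	pQTFQYSRGWTTa
F_arisanus	DH31	GGFGLDFGLNRGFSGAQAAKHLMGMAAANYAGGPa
F_arisanus	DH44	ISSLSITNPMDVLRQRFILELARRRQMQQQEQAKANREILNDIa
F_arisanus	ELN	GRQVRPLDCEKYVFHPHCRGTQA
F_arisanus	ETH	DEVPAFFLKIAKNVPRIa
F_arisanus	FMRFa	SQMGSSFIRFa
F_arisanus	FMRFa	SDVIIRFa
F_arisanus	ITG	ITQGQHNRNLLY
F_arisanus	kinin	NPSFSPWGa
F_arisanus	kinin	PARVPFNSWGa
F_arisanus	kinin	PFNSWGa
F_arisanus	MS	pQDVDHVFLRFa
F_arisanus	NTL	TIRQWTMQEPLYVEEPRWIPLDVKGDFNEEPGFNEEDPFILARa
F_arisanus	NTL	NKHSDIMDILNEPFFISRa
F_arisanus	NTL	GEIVEQLLKEQDPFYIARa
F_arisanus	NPLP1	SLATLAKNGDLPVSIQERAQDGQEDDE
F_arisanus	NPLP1	NLAALARESALPa
F_arisanus	NPLP1	NIASMAREFGLPTa
F_arisanus	NPLP1	NVGTLARDRQLPSa
F_arisanus	NPLP1	PSYTLGRLFVIPVATa
F_arisanus	NPLP1	NVGSLARDSALPPYa
F_arisanus	NPLP1	GIASLAKNGDFPFP
F_arisanus	NPLP1	NVGTLARDWSLPQTRHa
F_arisanus	OK-A	NIDEIDRAGFDSFS
F_arisanus	OK-A	NFDEIDRAGWDSFVK
F_arisanus	OK-B	NLDHIGGGNLL
F_arisanus	PVK	AAGILAQPRIa
F_arisanus	PVK	ADGAAGLVQYPRVa
F_arisanus	PK	HTTQFTPRLa
F_arisanus	PK	EFEDMTINHHQPPTPPPQFAPRLa
F_arisanus	PK	HLPFNPSPRLa
F_arisanus	trypto-PK	VDYDGDQPTSLDFNGLCNGGRCSETGDGIAGAMWFGPRLa
F_arisanus	RYa	NNFYTQGRYa
F_arisanus	RYa	PLFFPSRYa
F_arisanus	RYa	SIPNSDETSGGGSKIVEISPRPDRFYLGSRYa
F_arisanus	SIFa	AYRKPPFNGSIFa
F_arisanus	sNPF	SQRSPSLRLRFa
F_arisanus	TK	APMGFQGMRa
F_arisanus	TK	ASMGFHGMRa
F_arisanus	TK	ALPMGFQGMRa
F_arisanus	TK	APMGFQGVRa
F_arisanus	TK	GSMGFVGMRa
F_arisanus	TK	SARGVSGVRa
F_arisanus	TK	IPRWEMRGTFIGVRa
A_armilla	AKH	pQLNFSTGWa
A_armilla	AST-A	LPVYNFGIa
A_armilla	AST-A	SRTYSFGLa
A_armilla	AST-A	GRNYDFGLa
A_armilla	AST-A	AGYVYRFGLa
A_armilla	AST-A	PNEDVLHRYNFGIa
A_armilla	AST-CC	GQAKGRIYWRCYFNAVTCF
A_armilla	AST-CCC	SYWKQCAFNAVSCF
A_armilla	AT	GYKPEYISTAIGFa
A_armilla	CCAP	PFCNAFTGCa
A_armilla	CCHa-1	SCAQYGHSCWGGHa
A_armilla	CCHa-2	GCSAFGHSCFGGHa
A_armilla	CNMa	AKPASYMSLCYFKICNMa
A_armilla	CRZ	pQTFQYSHGWTNa
A_armilla	DH31	GLDLGLSRGFSGSQAAKHLMGLAAANYAGGPa
A_armilla	ELN	RMVDCERYPFHSTCRGTMS
A_armilla	FMRFa	...MGASFIRFa
A_armilla	FMRFa	FKSPDIVIRFa
A_armilla	FMRFa	ARSDLNFIRFa
A_armilla	ITG	ITGQGNRLF
A_armilla	MS	pQDVDHVFLRFa
A_armilla	NPF	EPEPMARPTRPKVITSPEELRRYLDSVKDFYTLNGKARYa
A_armilla	NPLP1	SLATLAKNDDLPVTIRD
A_armilla	NPLP1	NIASLARDYGLPSa
A_armilla	NPLP1	NVASLARDFALPNa
A_armilla	NPLP1	NIGAMAREHLLPMGa
A_armilla	NPLP1	NVASLARVYMLPQNa
A_armilla	NPLP1	NIAALARDYSLPSa
A_armilla	NPLP1	NIASLARNADWPGLA
A_armilla	OK-A	NIDEIDRTAFDSFF
A_armilla	OK-A	NFDEIDRDGFDGLDDFT
A_armilla	OK-B	NLDQIGGGNLV
A_armilla	OK-B	NLDHIGGGNLL
A_armilla	PDF	NSELINSLLGLPKNMNNAa
A_armilla	PVK	TAGLVPYPRIa
A_armilla	PVK	ASGLLHYPRVa
A_armilla	PVK	SSQGQLTLGGYTPRLa
A_armilla	PK	QSTSFTPRLa
A_armilla	PK	SPSLYSPRLa
A_armilla	trypto-PK	TTQEITSGMWFGPRLa
A_armilla	SIFa	AYKKPPFNGSIFa
A_armilla	sNPF	SQRSPSLRLRFa
A_armilla	SK	QQFDDYGHMRFa
A_armilla	SK	EKFDDYGHMRFa
A_armilla	TK	APMGFQGMRa
A_armilla	TK	AMMGFQGMRa
A_armilla	TK	AMMMGFQGMRa
A_armilla	TK	ARMGFQGMRa
A_armilla	TK	AIMGFHGMRa
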