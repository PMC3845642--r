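>Hs-RNase2 mature peptide of human RNase2/EDN (eosinophil-derived neurotoxin), UniProt P10153 residues 28-161
KPPQFTWAQWFETQHINMTSQQCTNAMQVINNYQRRCKNQNTFLLTTFANVVNVCGNPNM
TCPSNKTRKNCHHSGSQVPLIHCNLTTPSPQNISNCRYAQTPANMFYIVACDNRDQRRDP
PQYPVVPVHLDRII
>Hs-RNase3 mature peptide of human RNase3/ECP (eosinophil cationic protein), UniProt P12724 residues 28-160
RPPQFTRAQWFAIQHISLNPPRCTIAMRAINNYRWRCKNQNTFLRTTFANVVNVCGNQSI
RCPHNRTLNNCHRSRFRVPLLHCDLINPGAQNISNCRYADRPGRRFYVVACDNRDPRDSP
RYPVVPVHLDTTI
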