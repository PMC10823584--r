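# NetMHCpan version 4.1b

# Input is in PEPTIDE format

# Make EL predictions

HLA-A02:01 : Distance to training data  0.000 (using nearest neighbor HLA-A02:01)

# Rank Threshold for Strong binding peptides   0.500
# Rank Threshold for Weak binding peptides   2.000
---------------------------------------------------------------------------------------------------------------------------
 Pos          MHC         Peptide       Core Of Gp Gl Ip Il         Icore        Identity   Score_EL %Rank_EL BindLevel
---------------------------------------------------------------------------------------------------------------------------
   1  HLA-A*02:01       SLLMWITQV  SLLMWITQV  0  0  0  0  0     SLLMWITQV        PEPLIST  0.8563420    0.123 <= SB
   1  HLA-A*02:01       SLLMWITQC  SLLMWITQC  0  0  0  0  0     SLLMWITQC        PEPLIST  0.1095630    1.775 <= WB
   1  HLA-A*02:01        LLMWITQV   LLMWITQV  0  0  0  0  0      LLMWITQV        PEPLIST  0.0352160    4.582
---------------------------------------------------------------------------------------------------------------------------

Protein PEPLIST. Allele HLA-A*02:01. Number of high binders 1. Number of weak binders 1. Number of peptides 3

-----------------------------------------------------------------------------------
HLA-B07:02 : Distance to training data  0.000 (using nearest neighbor HLA-B07:02)

# Rank Threshold for Strong binding peptides   0.500
# Rank Threshold for Weak binding peptides   2.000
---------------------------------------------------------------------------------------------------------------------------
 Pos          MHC         Peptide       Core Of Gp Gl Ip Il         Icore        Identity   Score_EL %Rank_EL BindLevel
---------------------------------------------------------------------------------------------------------------------------
   1  HLA-B*07:02       SLLMWITQV  SLLMWITQV  0  0  0  0  0     SLLMWITQV        PEPLIST  0.0012330   23.000
   1  HLA-B*07:02       APRGPHGGA  APRGPHGGA  0  0  0  0  0     APRGPHGGA        PEPLIST  0.7216550    0.210 <= SB
---------------------------------------------------------------------------------------------------------------------------

Protein PEPLIST. Allele HLA-B*07:02. Number of high binders 1. Number of weak binders 0. Number of peptides 2
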