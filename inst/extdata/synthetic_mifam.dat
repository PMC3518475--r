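AC   MIPFS00001
ID   mir-501
MI   MI0000011  hsa-mir-501a
MI   MI0000012  hsa-mir-501b
MI   MI0000013  hsa-mir-501c
MI   MI0000014  hsa-mir-501d
MI   MI0000019  mmu-mir-501a
//
AC   MIPFS00002
ID   mir-502
MI   MI0000021  hsa-mir-502a
MI   MI0000022  hsa-mir-502b
MI   MI0000023  hsa-mir-502c
MI   MI0000024  hsa-mir-502d
MI   MI0000029  mmu-mir-502a
//
AC   MIPFS00003
ID   mir-503
MI   MI0000031  hsa-mir-503a
MI   MI0000032  hsa-mir-503b
MI   MI0000033  hsa-mir-503c
MI   MI0000034  hsa-mir-503d
MI   MI0000039  mmu-mir-503a
//
AC   MIPFS00004
ID   mir-504
MI   MI0000041  hsa-mir-504a
MI   MI0000042  hsa-mir-504b
MI   MI0000043  hsa-mir-504c
MI   MI0000044  hsa-mir-504d
MI   MI0000049  mmu-mir-504a
//
AC   MIPFS00005
ID   mir-505
MI   MI0000051  hsa-mir-505a
MI   MI0000052  hsa-mir-505b
MI   MI0000053  hsa-mir-505c
MI   MI0000054  hsa-mir-505d
MI   MI0000059  mmu-mir-505a
//
AC   MIPFS00006
ID   mir-506
MI   MI0000061  hsa-mir-506a
MI   MI0000062  hsa-mir-506b
MI   MI0000063  hsa-mir-506c
MI   MI0000064  hsa-mir-506d
MI   MI0000069  mmu-mir-506a
//
AC   MIPFS00007
ID   mir-507
MI   MI0000071  hsa-mir-507a
MI   MI0000072  hsa-mir-507b
MI   MI0000073  hsa-mir-507c
MI   MI0000074  hsa-mir-507d
MI   MI0000079  mmu-mir-507a
//
AC   MIPFS00008
ID   mir-508
MI   MI0000081  hsa-mir-508a
MI   MI0000082  hsa-mir-508b
MI   MI0000083  hsa-mir-508c
MI   MI0000084  hsa-mir-508d
MI   MI0000089  mmu-mir-508a
//
AC   MIPFS00009
ID   mir-509
MI   MI0000091  hsa-mir-509a
MI   MI0000092  hsa-mir-509b
MI   MI0000093  hsa-mir-509c
MI   MI0000094  hsa-mir-509d
MI   MI0000099  mmu-mir-509a
//
AC   MIPFS00010
ID   mir-510
MI   MI0000101  hsa-mir-510a
MI   MI0000102  hsa-mir-510b
MI   MI0000103  hsa-mir-510c
MI   MI0000104  hsa-mir-510d
MI   MI0000109  mmu-mir-510a
//
AC   MIPFS00011
ID   mir-511
MI   MI0000111  hsa-mir-511a
MI   MI0000112  hsa-mir-511b
MI   MI0000113  hsa-mir-511c
MI   MI0000114  hsa-mir-511d
MI   MI0000119  mmu-mir-511a
//
AC   MIPFS00012
ID   mir-512
MI   MI0000121  hsa-mir-512a
MI   MI0000122  hsa-mir-512b
MI   MI0000123  hsa-mir-512c
MI   MI0000124  hsa-mir-512d
MI   MI0000129  mmu-mir-512a
//
AC   MIPFS00013
ID   mir-513
MI   MI0000131  hsa-mir-513a
MI   MI0000132  hsa-mir-513b
MI   MI0000133  hsa-mir-513c
MI   MI0000134  hsa-mir-513d
MI   MI0000139  mmu-mir-513a
//
AC   MIPFS00014
ID   mir-514
MI   MI0000141  hsa-mir-514a
MI   MI0000142  hsa-mir-514b
MI   MI0000143  hsa-mir-514c
MI   MI0000144  hsa-mir-514d
MI   MI0000149  mmu-mir-514a
//
AC   MIPFS00015
ID   mir-515
MI   MI0000151  hsa-mir-515a
MI   MI0000152  hsa-mir-515b
MI   MI0000153  hsa-mir-515c
MI   MI0000154  hsa-mir-515d
MI   MI0000159  mmu-mir-515a
//
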