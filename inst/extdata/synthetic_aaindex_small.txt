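H SYNT000001
D Synthetic index 1 (pseudo-random values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    -1.004   0.263  -0.158   1.774   0.234   0.637  -1.164   1.429  -1.651  -0.720
     0.180   0.193  -0.403   1.480   0.247  -0.059  -0.778   1.022  -1.828   4.621
//
H SYNT000002
D Synthetic index 2 (pseudo-random values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    -0.876   1.528   0.524   1.547  -1.629  -0.877  -1.440   0.462  -2.315   0.494
    -0.182   3.515  -0.276  -0.222  -1.380  -0.444   0.366   0.835   2.131   1.940
//
H SYNT000003
D Synthetic index 3 (pseudo-random values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    -0.203   2.806  -3.554   1.246  -1.045   2.644  -0.727   2.638   0.088  -3.757
    -0.894  -3.477   0.358   3.795  -4.544   1.961  -2.798   3.650   2.763  -1.678
//
H SYNT000004
D Synthetic index 4 (pseudo-random values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    -0.524  -0.138  -0.758   5.164   0.260  -1.426   1.276   0.403  -0.140  -0.185
     0.898  -2.129  -2.325   3.297  -4.124   0.025  -2.175   0.541   2.017  -4.149
//
H SYNT000005
D Synthetic index 5 (pseudo-random values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.794  -0.100  -2.691  -3.862   1.419  -0.316   0.433   1.635   3.454  -0.208
    -1.114   2.857  -1.786  -2.315  -1.061   4.891  -1.665   0.827  -2.357  -2.348
//
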