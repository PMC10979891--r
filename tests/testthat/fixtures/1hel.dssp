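==== Secondary structure and accessibility for 1HEL (hen egg-white lysozyme) ====
REMARK generated with the MDTraj implementations of Kabsch-Sander DSSP (SS codes)
REMARK and Shrake-Rupley solvent accessibility (ACC column, probe 1.4 A, 960 points)
  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA
    1    1 A K                      79
    2    2 A V  B                  100
    3    3 A F                      17
    4    4 A G                      33
    5    5 A R  H                   81
    6    6 A C  H                   44
    7    7 A E  H                   89
    8    8 A L  H                    1
    9    9 A A  H                    0
   10   10 A A  H                   41
   11   11 A A  H                   21
   12   12 A M  H                    2
   13   13 A K  H                   86
   14   14 A R  H                  192
   15   15 A H  T                   37
   16   16 A G  T                   36
   17   17 A L                       0
   18   18 A D  T                   63
   19   19 A N  T                   89
   20   20 A Y  B                   65
   21   21 A R  T                  140
   22   22 A G  T                   66
   23   23 A Y  B                   45
   24   24 A S                      40
   25   25 A L  H                    5
   26   26 A G  H                    3
   27   27 A N  H                   19
   28   28 A W  H                    0
   29   29 A V  H                    0
   30   30 A C  H                    1
   31   31 A A  H                    0
   32   32 A A  H                    0
   33   33 A K  H                   61
   34   34 A F  H                   64
   35   35 A E  H                   34
   36   36 A S  H                   11
   37   37 A N  T                   88
   38   38 A F  T                   14
   39   39 A N  B                   47
   40   40 A T  T                    1
   41   41 A Q  T                  126
   42   42 A A                      17
   43   43 A T  E                   67
   44   44 A N  E                   73
   45   45 A R  E                  143
   46   46 A N                      52
   47   47 A T  T                  153
   48   48 A D  T                   88
   49   49 A G  S                   25
   50   50 A S                       1
   51   51 A T  E                    4
   52   52 A D  E                   26
   53   53 A Y  E                   24
   54   54 A G  T                    0
   55   55 A I  T                    4
   56   56 A L  T                    1
   57   57 A Q  T                   17
   58   58 A I  E                    2
   59   59 A N  E                   28
   60   60 A S  T                    0
   61   61 A R  T                   47
   62   62 A W  T                  110
   63   63 A W  T                   32
   64   64 A C                       0
   65   65 A N  B                   75
   66   66 A D                      39
   67   67 A G  S                   68
   68   68 A R                     119
   69   69 A T                      12
   70   70 A P  T                  111
   71   71 A G  T                   65
   72   72 A S                      36
   73   73 A R                     161
   74   74 A N                      44
   75   75 A L  T                   96
   76   76 A C  T                   28
   77   77 A N                     123
   78   78 A I  S                   29
   79   79 A P  B                   73
   80   80 A C  G                    2
   81   81 A S  G                   83
   82   82 A A  G                   34
   83   83 A L  G                    3
   84   84 A L  G                   45
   85   85 A S  S                   49
   86   86 A S  S                   68
   87   87 A D  S                   92
   88   88 A I                       9
   89   89 A T  H                   46
   90   90 A A  H                   30
   91   91 A S  H                    5
   92   92 A V  H                    3
   93   93 A N  H                   83
   94   94 A C  H                    3
   95   95 A A  H                    0
   96   96 A K  H                   42
   97   97 A K  H                  134
   98   98 A I  H                   12
   99   99 A V  H                    7
  100  100 A S  H                   44
  101  101 A D  T                  105
  102  102 A G  S                   61
  103  103 A N  S                  115
  104  104 A G  G                    9
  105  105 A M  G                    0
  106  106 A N  G                   45
  107  107 A A  G                   61
  108  108 A W  S                   10
  109  109 A V  H                   76
  110  110 A A  H                   13
  111  111 A W  H                   15
  112  112 A R  H                  109
  113  113 A N  H                  112
  114  114 A R  H                  127
  115  115 A C  T                    0
  116  116 A K  T                  101
  117  117 A G  T                   86
  118  118 A T  S                   67
  119  119 A D                     108
  120  120 A V  G                   16
  121  121 A Q  G                  124
  122  122 A A  G                   36
  123  123 A W  G                   57
  124  124 A I  G                   40
  125  125 A R  T                  165
  126  126 A G  T                   79
  127  127 A C                      25
  128  128 A R                     224
  129  129 A L                      94
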