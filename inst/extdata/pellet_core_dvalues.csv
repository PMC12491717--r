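fraction,method,d10_um,d50_um,d90_um,span
250-355,CNN,260.38,314.78,382.87,0.39
250-355,DIA,255.68,317.20,388.34,0.42
250-355,LD,249.23,317.49,398.08,0.47
355-500,CNN,369.52,442.73,528.57,0.36
355-500,DIA,374.31,433.21,501.46,0.29
355-500,LD,356.55,435.36,537.05,0.41
500-600,CNN,449.83,532.12,631.41,0.34
500-600,DIA,458.01,536.61,627.57,0.32
500-600,LD,419.25,527.70,640.12,0.42
600-710,CNN,539.65,632.58,740.85,0.32
600-710,DIA,546.97,635.05,732.59,0.29
600-710,LD,531.43,631.09,753.08,0.35
710-850,CNN,677.03,773.47,883.49,0.27
710-850,DIA,647.59,753.65,866.57,0.29
710-850,LD,635.42,766.02,889.56,0.33
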