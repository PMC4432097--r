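<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="420" height="240" viewBox="0 0 420 240">
<rect class="background" x="0" y="0" width="420" height="240" fill="#ffffff"/>
<g class="series-layer">
<g class="series" id="series--series-1" stroke="#1f77b4" fill="none" stroke-width="1">
<polyline points="64.87,178.37 65.74,180.31 66.61,179.53 67.04,180.25 68.78,179.91 69.87,178.98 70.96,178.80 71.83,180.01 72.48,180.55 73.35,179.04 74.22,179.53 75.31,180.09 76.18,179.89 77.05,178.88 78.79,179.67 79.22,179.05 80.96,180.83 81.40,179.31 82.05,178.43 83.14,180.68 84.66,181.45 85.10,177.27 86.18,180.77 87.92,180.17 88.79,178.98 89.44,179.31 90.75,180.98 91.18,179.43 92.71,179.35 93.58,180.95 94.23,179.19 95.53,178.99 96.40,179.72 97.27,178.64 98.14,180.06 99.23,180.44 100.10,179.98 101.41,180.59 102.71,178.47 103.80,178.14 104.89,181.81 105.54,178.16 106.84,178.89 107.93,172.44 108.37,180.14 109.45,179.22 110.98,179.10 111.41,180.60 112.93,178.15 113.15,179.55 114.89,179.17 115.54,180.87 116.41,179.62 117.28,179.49 118.37,180.16 119.46,179.16 120.11,179.06 121.85,177.60 122.94,180.33 123.37,177.93 124.24,179.77 125.11,179.90 126.42,179.59 127.94,180.14 128.59,180.71 129.03,179.52 130.11,178.48 131.42,179.92 132.29,179.59 133.81,180.03 134.90,179.37 135.55,179.10 136.86,179.32 137.29,179.81 138.81,181.14 139.25,178.37 140.12,178.73 141.86,180.75 142.29,177.65 143.81,180.12 144.03,179.04 145.55,179.45 146.64,179.12 147.08,180.86 148.38,178.93 149.03,181.36 150.77,178.87 151.86,179.73 152.51,180.34 153.17,178.19 154.25,179.71 155.78,178.94 156.21,179.54 157.30,145.85 158.82,178.69 159.26,176.88 161.00,179.15 161.21,179.91 162.30,179.99 163.82,180.40 164.91,179.90 166.00,180.17 166.87,179.29 167.52,179.72 168.39,179.54 169.04,180.75 170.56,179.42 171.43,177.89 172.74,178.77 173.61,176.55 174.48,180.43 175.57,179.25 176.65,179.09 177.74,178.75 178.18,179.06 179.05,179.07 180.57,178.91 181.87,179.62 182.74,180.20 183.83,181.15 184.92,178.39 185.57,179.63 186.66,180.38 187.09,179.51 188.40,180.12 189.48,178.85 190.57,179.59 191.22,178.81 192.75,177.92 193.18,179.40 194.49,179.57 195.57,180.07 196.88,180.15 197.53,179.04 198.84,179.84 199.49,180.03 200.36,179.80 201.88,179.15 202.97,179.98 203.40,179.21 204.06,178.80 205.36,179.93 206.23,180.02 207.97,179.27 208.41,179.23 209.06,180.88 210.15,179.92 211.89,179.58 212.97,158.70 213.19,46.91 214.28,177.05 215.36,178.70 216.45,178.78 217.32,178.90 218.84,180.38 219.50,179.89 220.80,178.59 221.67,180.03 222.32,180.52 223.85,180.53 224.28,179.16 225.80,179.91 226.89,180.48 227.11,178.83 228.63,180.46 229.50,180.01 230.15,179.89 231.24,178.40 232.33,180.85 233.20,173.28 234.07,180.62 235.37,179.15 236.03,178.66 237.77,176.58 238.20,181.25 239.07,179.93 240.81,179.88 241.90,179.65 242.33,179.95 243.20,180.87 244.07,179.55 245.81,179.74 246.25,179.32 247.99,179.08 248.64,179.04 249.29,180.70 250.38,179.08 251.47,178.34 252.12,177.37 253.42,178.95 254.95,179.19 255.16,177.23 256.25,177.98 257.99,179.22 258.43,179.42 259.73,178.92 260.82,179.65 261.69,179.78 262.12,179.69 263.43,179.61 264.52,179.24 265.82,179.41 266.47,178.49 267.99,179.15 268.21,179.46 269.73,178.59 270.39,178.97 271.47,178.23 273.00,178.56 273.21,165.37 274.30,175.96 275.82,179.22 276.48,178.14 278.00,148.69 278.22,54.13 279.09,178.13 280.17,179.72 281.48,178.85 282.13,178.20 283.00,179.87 284.96,178.70 285.18,180.93 286.70,180.01 287.79,180.38 288.66,180.08 289.53,178.67 290.61,180.81 291.92,180.18 292.35,178.96 293.87,173.35 294.53,180.32 295.40,180.71 296.48,179.61 297.79,180.25 298.44,174.52 299.75,180.07 300.62,179.38 301.70,179.49 302.36,179.80 303.66,178.54 304.10,152.84 305.84,180.64 306.05,178.73 307.79,179.48 308.23,179.64 309.32,177.91 310.62,177.36 311.06,178.35 312.58,178.52 313.88,180.00 314.10,180.28 315.62,178.45 316.06,178.93 317.80,181.52 318.88,179.86 319.54,178.94 320.41,180.34 321.71,179.67 322.15,178.59 323.45,179.47 324.10,177.89 325.63,179.35 326.93,180.07 327.80,179.13 328.24,178.76 329.32,179.96 330.85,178.76 331.93,178.53 332.80,179.22 333.67,178.16 334.76,174.17 335.63,179.39 336.94,180.62 337.37,179.07 338.68,180.47 339.33,178.22 340.20,178.92 341.72,179.29 342.81,179.45 343.68,179.91 344.55,178.53 345.42,180.96 346.94,178.61 347.37,179.92 348.90,179.02 349.55,180.13 350.64,179.98 351.94,179.76 352.81,179.82 353.68,179.95 354.33,180.15 355.64,178.83 356.73,181.10 357.60,180.69 358.25,180.51 359.77,179.25 360.64,179.29 361.95,172.17 362.16,129.74 363.47,179.40 364.12,179.54 365.86,177.42 366.73,180.63 367.38,179.44 368.47,180.25 369.56,180.62 370.43,181.31 371.51,179.71 372.38,179.31 373.69,177.66 374.78,179.92 375.43,179.02 376.95,180.21 377.60,180.90 378.47,179.11 379.34,180.33 380.43,178.81 381.30,178.41 382.61,179.98 383.26,179.23 384.78,179.26 385.22,180.70 386.52,179.81 387.61,179.55 388.26,178.88 389.35,179.43"/>
</g>
</g>
<g class="axes" stroke="#333333" stroke-width="1" font-family="sans-serif" font-size="11" fill="none">
<line x1="64.00" y1="192.00" x2="390.00" y2="192.00"/>
<line x1="64.00" y1="40.00" x2="64.00" y2="192.00"/>
<line x1="64.00" y1="192.00" x2="64.00" y2="197.00"/>
<text x="64.00" y="208.00" fill="#333333" stroke="none" text-anchor="middle">0</text>
<line x1="172.67" y1="192.00" x2="172.67" y2="197.00"/>
<text x="172.67" y="208.00" fill="#333333" stroke="none" text-anchor="middle">20</text>
<line x1="281.33" y1="192.00" x2="281.33" y2="197.00"/>
<text x="281.33" y="208.00" fill="#333333" stroke="none" text-anchor="middle">40</text>
<line x1="390.00" y1="192.00" x2="390.00" y2="197.00"/>
<text x="390.00" y="208.00" fill="#333333" stroke="none" text-anchor="middle">60</text>
<line x1="59.00" y1="45.27" x2="64.00" y2="45.27"/>
<text x="56.00" y="49.12" fill="#333333" stroke="none" text-anchor="end">1</text>
<line x1="59.00" y1="113.10" x2="64.00" y2="113.10"/>
<text x="56.00" y="116.95" fill="#333333" stroke="none" text-anchor="end">0.5</text>
<line x1="59.00" y1="180.94" x2="64.00" y2="180.94"/>
<text x="56.00" y="184.79" fill="#333333" stroke="none" text-anchor="end">0</text>
<text x="227.00" y="232.00" fill="#333333" stroke="none" text-anchor="middle">Time</text>
<text x="14.00" y="116.00" fill="#333333" stroke="none" text-anchor="middle" transform="rotate(-90 14.00 116.00)">Amplitude</text>
<text x="227.00" y="28.00" fill="#333333" stroke="none" text-anchor="middle" font-size="14" font-weight="bold">Time series</text>
</g>
</svg>
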