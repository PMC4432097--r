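<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="420" height="260" viewBox="0 0 420 260">
<rect class="background" x="0" y="0" width="420" height="260" fill="#ffffff"/>
<g class="series-layer">
<g class="series" id="series--series-1" stroke="#1f77b4" fill="none" stroke-width="1">
<polyline points="389.67,202.58 388.21,202.93 387.39,202.68 386.49,202.73 385.11,202.70 384.29,202.73 383.23,202.59 382.09,202.33 381.03,202.99 380.71,202.72 379.24,202.80 378.18,202.72 377.53,202.64 376.47,202.95 375.08,202.52 374.43,202.53 373.94,202.71 372.39,202.74 371.66,202.53 370.92,202.76 369.21,202.76 368.32,202.40 367.74,202.47 366.60,202.85 365.22,202.60 364.40,202.85 363.18,202.74 362.69,202.79 361.79,202.57 360.65,202.40 359.02,202.74 358.37,202.69 357.47,202.68 356.58,202.52 355.84,202.70 354.29,202.22 353.64,202.73 352.17,202.88 351.44,202.72 350.06,202.70 349.73,202.33 348.91,201.94 347.20,201.43 346.14,191.46 345.98,192.40 344.67,201.76 343.86,202.49 342.96,202.50 341.74,202.38 340.03,202.75 339.95,202.68 338.32,202.73 337.50,202.65 336.03,202.78 335.87,202.77 334.48,203.02 333.67,202.61 332.85,202.69 331.22,202.62 330.90,202.95 329.92,202.75 328.86,202.67 327.31,202.57 326.33,202.93 325.52,202.63 324.87,202.15 323.32,202.86 322.50,202.83 321.03,202.72 320.79,202.71 319.48,202.33 318.34,202.30 317.94,202.47 316.63,202.68 315.25,202.84 314.10,202.58 313.53,202.74 312.23,202.54 311.17,202.05 310.11,202.41 309.95,202.83 308.24,202.52 307.18,202.61 306.52,202.90 305.46,202.58 304.40,202.63 304.00,202.78 302.04,202.19 301.31,202.59 300.41,202.31 299.27,201.98 298.05,200.09 297.07,184.06 296.74,164.09 295.93,197.17 294.95,201.94 293.24,202.24 292.50,202.20 291.93,202.59 290.95,202.51 289.57,202.50 288.91,202.45 287.53,202.66 286.80,202.47 285.90,202.72 284.84,202.55 283.94,202.57 282.07,202.84 281.74,202.85 280.68,202.63 279.13,202.75 278.81,202.80 277.09,202.76 276.85,202.31 275.87,202.95 274.40,202.73 273.91,202.35 272.12,202.67 271.06,202.51 270.33,202.69 269.76,202.70 268.45,202.60 267.64,202.25 266.66,202.64 265.52,202.75 264.21,202.60 263.40,202.32 262.58,202.52 261.36,202.17 260.46,202.41 259.65,202.75 258.34,202.22 257.45,202.40 256.31,202.15 255.74,201.76 254.76,202.39 253.29,202.22 252.56,202.09 251.25,202.33 250.76,201.78 249.95,202.11 248.15,201.47 247.83,201.20 246.36,200.43 245.06,199.69 244.24,197.28 243.02,191.52 242.04,171.50 241.06,72.99 240.74,47.82 239.92,146.46 238.94,186.11 237.96,194.79 236.82,198.75 235.76,200.34 234.70,201.18 233.89,201.62 232.83,201.69 231.20,201.71 230.87,202.01 229.49,202.37 228.75,202.60 227.20,202.32 226.47,202.30 225.41,202.39 224.19,202.15 223.21,202.40 222.31,202.34 221.01,197.88 220.76,183.73 219.87,202.41 218.64,202.68 217.26,202.42 216.52,202.30 215.63,202.44 214.24,202.12 213.18,202.61 212.77,202.79 211.80,202.35 210.25,202.35 209.02,202.67 208.13,202.59 207.31,201.97 206.17,202.52 205.44,202.51 204.05,202.58 203.40,202.59 202.26,202.62 201.52,202.33 200.95,202.62 199.73,202.57 198.75,202.31 197.29,202.48 196.80,202.74 195.98,202.56 194.03,202.42 193.13,202.29 192.80,202.46 191.99,202.53 190.68,202.01 189.30,202.26 188.73,202.44 187.10,202.16 186.04,201.79 185.71,201.75 184.08,201.16 183.26,200.51 182.04,198.54 181.06,188.03 180.82,186.32 179.92,194.72 178.05,191.95 177.07,174.94 176.01,65.09 175.85,51.38 174.95,155.00 173.97,188.51 172.99,196.77 171.93,198.98 170.87,200.72 169.89,201.05 168.43,201.61 167.94,201.80 166.80,201.98 165.41,201.99 164.19,202.21 163.13,201.94 162.56,201.97 161.91,202.14 160.11,183.33 159.95,195.13 158.07,201.51 157.01,201.00 156.12,198.71 155.47,195.93 154.98,199.48 153.75,201.66 152.86,201.47 151.06,200.14 150.00,169.09 149.84,163.91 148.94,198.34 147.64,201.52 146.58,202.23 145.60,202.33 144.87,202.35 143.97,202.21 142.50,202.35 141.85,202.49 140.79,202.62 139.90,202.67 138.92,202.62 137.37,202.83 136.96,202.86 135.90,202.73 134.68,202.45 133.46,202.63 132.31,202.60 131.34,202.46 130.03,202.49 129.62,202.52 128.32,202.66 127.50,202.74 126.53,202.81 125.96,202.04 124.16,202.20 123.35,202.12 122.12,202.19 121.15,201.85 120.00,199.15 119.35,193.07 118.94,195.40 117.80,200.84 116.99,201.64 115.44,202.31 114.71,202.56 113.24,202.66 112.99,202.69 111.12,202.28 110.96,202.54 109.73,202.47 108.10,202.49 107.53,202.64 106.80,202.77 105.09,202.56 104.27,202.45 103.05,202.45 102.23,202.39 101.09,202.02 100.52,202.25 99.14,202.15 98.65,202.19 97.02,201.75 96.04,201.15 95.06,200.47 94.08,198.43 93.02,188.67 92.04,140.42 91.80,128.32 90.98,174.25 89.92,196.01 88.78,199.57 87.72,201.01 86.66,201.48 85.20,201.95 84.62,201.44 83.81,201.85 82.99,202.19 81.12,202.59 80.30,202.11 79.16,202.40 78.92,202.52 77.37,202.49 76.39,202.57 75.49,202.62 74.92,202.52 73.54,202.75 72.07,202.72 71.74,202.61 70.68,202.70 69.46,202.59 68.89,202.77 67.26,202.64 66.28,202.42 65.71,202.86 64.08,202.71"/>
</g>
</g>
<g class="legend" font-family="sans-serif" font-size="11">
<rect x="293.20" y="48.00" width="88.80" height="27.00" fill="#ffffff" stroke="#333333" fill-opacity="0.8"/>
<g class="legend-entry">
<line x1="301.20" y1="61.50" x2="315.20" y2="61.50" stroke="#1f77b4" stroke-width="2"/>
<text x="321.20" y="65.35" fill="#333333">series-1</text>
</g>
</g>
<g class="axes" stroke="#333333" stroke-width="1" font-family="sans-serif" font-size="11" fill="none">
<line x1="64.00" y1="212.00" x2="390.00" y2="212.00"/>
<line x1="64.00" y1="40.00" x2="64.00" y2="212.00"/>
<line x1="64.00" y1="212.00" x2="64.00" y2="217.00"/>
<text x="64.00" y="228.00" fill="#333333" stroke="none" text-anchor="middle">10</text>
<line x1="227.00" y1="212.00" x2="227.00" y2="217.00"/>
<text x="227.00" y="228.00" fill="#333333" stroke="none" text-anchor="middle">5</text>
<line x1="390.00" y1="212.00" x2="390.00" y2="217.00"/>
<text x="390.00" y="228.00" fill="#333333" stroke="none" text-anchor="middle">0</text>
<line x1="59.00" y1="47.90" x2="64.00" y2="47.90"/>
<text x="56.00" y="51.75" fill="#333333" stroke="none" text-anchor="end">1</text>
<line x1="59.00" y1="125.53" x2="64.00" y2="125.53"/>
<text x="56.00" y="129.38" fill="#333333" stroke="none" text-anchor="end">0.5</text>
<line x1="59.00" y1="203.17" x2="64.00" y2="203.17"/>
<text x="56.00" y="207.02" fill="#333333" stroke="none" text-anchor="end">0</text>
<text x="227.00" y="252.00" fill="#333333" stroke="none" text-anchor="middle">Chemical shift [ppm]</text>
<text x="14.00" y="126.00" fill="#333333" stroke="none" text-anchor="middle" transform="rotate(-90 14.00 126.00)">Intensity</text>
<text x="227.00" y="28.00" fill="#333333" stroke="none" text-anchor="middle" font-size="14" font-weight="bold">1D NMR</text>
</g>
</svg>
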