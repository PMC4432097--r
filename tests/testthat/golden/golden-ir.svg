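<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="420" height="260" viewBox="0 0 420 260">
<rect class="background" x="0" y="0" width="420" height="260" fill="#ffffff"/>
<g class="series-layer">
<g class="series" id="series--series-1" stroke="#1f77b4" fill="none" stroke-width="1">
<polyline points="389.02,49.76 388.37,49.73 387.23,50.71 386.25,50.96 385.43,49.68 384.78,50.65 383.48,49.44 382.17,49.98 381.52,49.80 380.87,50.21 379.40,49.83 378.75,49.62 377.77,50.07 376.30,50.04 375.65,49.76 374.67,50.31 373.53,49.80 372.39,49.86 371.41,49.83 370.27,50.30 369.29,50.19 368.15,49.95 367.33,49.61 366.68,50.67 365.54,50.19 364.89,49.86 363.25,50.16 362.93,50.20 361.13,50.80 360.65,50.94 359.01,52.25 358.20,53.52 357.06,55.09 356.08,57.17 355.26,60.13 354.12,62.58 353.14,66.59 352.00,70.96 351.02,76.26 350.05,80.61 349.07,84.16 348.25,86.66 347.11,89.15 346.95,90.55 345.97,89.48 344.99,88.81 343.85,86.07 342.87,82.55 341.89,78.62 340.91,74.72 339.93,70.37 338.96,65.58 337.65,61.56 337.00,58.67 335.86,55.79 334.72,53.75 333.74,52.21 332.43,51.55 331.45,51.42 330.48,50.99 329.01,50.53 328.68,50.02 327.05,50.05 326.24,50.43 325.26,50.60 324.77,49.84 323.95,50.16 322.97,49.75 321.34,49.93 320.04,50.39 319.55,49.88 318.41,49.88 317.43,50.04 316.29,50.44 315.15,50.45 314.00,54.25 313.03,59.72 312.05,72.33 311.07,89.94 310.09,113.85 309.11,140.60 308.13,165.64 307.15,177.59 306.67,179.93 305.85,174.28 304.87,155.14 303.89,127.93 302.91,101.49 301.94,79.96 300.96,66.57 299.00,64.97 298.02,86.42 297.04,108.75 296.88,110.56 295.90,99.52 294.92,71.25 293.94,55.37 292.64,50.29 291.34,50.14 290.68,49.67 289.05,49.62 288.07,49.84 287.42,49.98 286.61,49.53 285.14,49.68 284.65,49.64 283.18,50.11 282.20,50.06 281.39,50.01 280.90,49.72 279.76,50.71 278.13,50.07 277.31,49.74 276.17,49.64 275.19,49.44 274.86,50.26 273.72,49.66 272.09,49.73 271.44,49.81 270.46,50.54 269.97,49.63 268.34,49.76 267.85,49.59 266.22,49.73 265.41,49.87 264.92,50.01 263.45,50.27 262.96,49.82 261.33,49.95 260.51,50.45 259.05,50.35 258.56,49.46 257.90,50.09 256.93,50.63 255.29,50.41 254.48,50.31 253.17,50.48 252.20,51.48 251.05,52.67 250.08,55.01 249.10,58.17 248.12,64.48 247.14,73.78 246.16,85.51 245.02,105.09 244.04,123.91 243.06,143.29 242.09,160.16 241.11,170.86 240.13,174.60 239.80,173.37 238.99,167.66 237.84,152.47 236.87,136.06 235.89,119.56 234.91,105.45 233.93,93.44 232.95,84.52 231.97,79.31 230.02,78.55 229.04,83.24 228.06,92.29 227.08,102.19 226.10,114.54 225.12,128.00 224.15,140.10 223.00,152.58 222.03,159.87 221.05,163.38 220.72,163.31 219.91,161.89 218.93,155.77 217.95,145.92 216.97,134.00 215.99,121.19 214.85,104.65 213.87,92.65 212.89,82.41 211.91,72.73 210.94,66.20 209.96,59.66 208.82,56.55 207.84,52.90 206.70,51.76 205.88,50.67 204.90,50.43 203.60,49.93 202.13,50.26 201.80,49.87 200.99,50.22 199.68,50.22 198.71,49.90 197.89,49.85 196.42,49.59 195.93,49.97 194.30,49.78 193.49,50.49 192.51,50.38 191.04,51.53 190.23,53.17 189.08,54.12 188.11,59.11 187.13,63.33 186.15,71.26 185.01,81.79 184.03,94.65 183.05,108.34 182.07,123.70 181.09,138.61 180.11,152.87 179.14,164.12 178.16,171.81 177.02,177.10 176.20,178.54 175.71,177.43 174.90,173.06 173.92,166.51 172.94,155.58 171.96,142.70 170.98,127.96 169.84,112.05 168.86,99.21 167.88,86.38 166.90,77.21 165.93,69.19 164.95,63.31 163.15,58.87 162.01,78.05 161.03,121.93 160.06,152.07 159.89,152.00 158.91,126.46 157.12,107.77 156.14,114.79 155.65,116.66 155.00,114.27 153.86,103.24 152.88,90.29 151.90,78.87 150.92,74.23 149.78,72.19 148.97,64.32 147.99,56.20 146.68,51.04 145.87,50.56 144.56,50.30 143.09,50.12 142.12,50.28 141.95,50.02 140.65,49.72 139.34,49.92 138.20,49.93 137.39,49.65 136.08,49.89 135.76,49.85 134.45,50.00 133.64,50.27 132.66,50.09 131.84,50.11 130.05,50.30 129.23,49.86 128.09,50.68 127.28,52.03 126.13,55.78 125.16,63.20 124.01,76.16 123.04,92.02 122.06,110.94 121.08,128.88 120.10,142.04 119.45,145.62 118.96,145.19 117.98,136.21 116.84,118.23 115.86,98.45 114.88,80.89 113.90,68.30 112.92,58.28 111.78,53.57 110.97,50.60 109.83,50.81 108.36,50.27 107.87,50.95 106.24,51.82 105.59,52.74 104.12,55.85 103.14,58.88 102.16,63.63 101.02,70.76 100.04,79.32 99.06,90.02 98.08,102.61 97.11,118.10 96.13,133.04 95.15,149.81 94.01,169.53 93.03,185.74 92.05,199.45 91.40,203.72 90.09,203.51 89.11,203.64 88.79,203.42 87.97,203.68 86.99,204.18 85.20,203.81 84.22,203.89 83.73,203.79 82.92,197.10 81.94,181.05 80.96,162.99 79.98,145.45 78.84,124.91 77.86,108.80 76.88,96.29 75.90,83.58 74.93,74.61 73.95,66.40 72.97,61.29 71.99,57.27 70.85,53.99 69.87,51.96 68.73,51.28 67.91,50.58 66.94,50.69 65.47,50.40 64.49,50.14"/>
</g>
</g>
<g class="axes" stroke="#333333" stroke-width="1" font-family="sans-serif" font-size="11" fill="none">
<line x1="64.00" y1="212.00" x2="390.00" y2="212.00"/>
<line x1="64.00" y1="40.00" x2="64.00" y2="212.00"/>
<line x1="64.00" y1="212.00" x2="64.00" y2="217.00"/>
<text x="64.00" y="228.00" fill="#333333" stroke="none" text-anchor="middle">4000</text>
<line x1="154.56" y1="212.00" x2="154.56" y2="217.00"/>
<text x="154.56" y="228.00" fill="#333333" stroke="none" text-anchor="middle">3000</text>
<line x1="245.11" y1="212.00" x2="245.11" y2="217.00"/>
<text x="245.11" y="228.00" fill="#333333" stroke="none" text-anchor="middle">2000</text>
<line x1="335.67" y1="212.00" x2="335.67" y2="217.00"/>
<text x="335.67" y="228.00" fill="#333333" stroke="none" text-anchor="middle">1000</text>
<line x1="59.00" y1="49.31" x2="64.00" y2="49.31"/>
<text x="56.00" y="53.16" fill="#333333" stroke="none" text-anchor="end">1</text>
<line x1="59.00" y1="127.81" x2="64.00" y2="127.81"/>
<text x="56.00" y="131.66" fill="#333333" stroke="none" text-anchor="end">0.5</text>
<line x1="59.00" y1="206.31" x2="64.00" y2="206.31"/>
<text x="56.00" y="210.16" fill="#333333" stroke="none" text-anchor="end">0</text>
<text x="227.00" y="252.00" fill="#333333" stroke="none" text-anchor="middle">Wavenumber [1/cm]</text>
<text x="14.00" y="126.00" fill="#333333" stroke="none" text-anchor="middle" transform="rotate(-90 14.00 126.00)">Transmittance</text>
<text x="227.00" y="28.00" fill="#333333" stroke="none" text-anchor="middle" font-size="14" font-weight="bold">IR</text>
</g>
</svg>
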