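<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="420" height="300" viewBox="0 0 420 300">
<rect class="background" x="0" y="0" width="420" height="300" fill="#ffffff"/>
<g class="series-layer">
<g class="series" id="series--series-1" stroke="#1f77b4" fill="none" stroke-width="1">
<circle cx="390.00" cy="151.06" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="377.39" cy="126.41" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="371.22" cy="228.89" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="369.76" cy="137.70" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="327.78" cy="215.03" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="316.74" cy="195.46" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="255.02" cy="210.07" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="253.39" cy="126.00" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="248.82" cy="185.04" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="232.96" cy="49.64" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="218.13" cy="214.41" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="188.85" cy="50.31" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="183.37" cy="90.13" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="166.08" cy="229.06" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="161.02" cy="170.46" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="154.74" cy="124.30" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="120.98" cy="135.47" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="94.52" cy="56.29" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="90.64" cy="242.36" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="83.50" cy="134.67" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="82.64" cy="239.19" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="81.58" cy="225.31" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="79.19" cy="176.06" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="67.84" cy="241.85" r="2.5" fill="#1f77b4" stroke="none"/>
<circle cx="64.00" cy="171.86" r="2.5" fill="#1f77b4" stroke="none"/>
</g>
</g>
<g class="axes" stroke="#333333" stroke-width="1" font-family="sans-serif" font-size="11" fill="none">
<line x1="64.00" y1="252.00" x2="390.00" y2="252.00"/>
<line x1="64.00" y1="40.00" x2="64.00" y2="252.00"/>
<line x1="239.83" y1="252.00" x2="239.83" y2="257.00"/>
<text x="239.83" y="268.00" fill="#333333" stroke="none" text-anchor="middle">5</text>
<line x1="59.00" y1="48.85" x2="64.00" y2="48.85"/>
<text x="56.00" y="52.70" fill="#333333" stroke="none" text-anchor="end">0</text>
<line x1="59.00" y1="110.97" x2="64.00" y2="110.97"/>
<text x="56.00" y="114.82" fill="#333333" stroke="none" text-anchor="end">50</text>
<line x1="59.00" y1="173.08" x2="64.00" y2="173.08"/>
<text x="56.00" y="176.93" fill="#333333" stroke="none" text-anchor="end">100</text>
<line x1="59.00" y1="235.20" x2="64.00" y2="235.20"/>
<text x="56.00" y="239.05" fill="#333333" stroke="none" text-anchor="end">150</text>
<text x="227.00" y="292.00" fill="#333333" stroke="none" text-anchor="middle">F2 [ppm]</text>
<text x="14.00" y="146.00" fill="#333333" stroke="none" text-anchor="middle" transform="rotate(-90 14.00 146.00)">F1 [ppm]</text>
<text x="227.00" y="28.00" fill="#333333" stroke="none" text-anchor="middle" font-size="14" font-weight="bold">2D NMR</text>
</g>
</svg>
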