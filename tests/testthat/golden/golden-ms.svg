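<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="460" height="260" viewBox="0 0 460 260">
<rect class="background" x="0" y="0" width="460" height="260" fill="#ffffff"/>
<g class="series-layer">
<g class="series" id="series--series-1" stroke="#1f77b4" fill="none" stroke-width="1">
<line x1="64.00" y1="212.00" x2="64.00" y2="209.33"/>
<line x1="119.08" y1="212.00" x2="119.08" y2="176.54"/>
<line x1="133.09" y1="212.00" x2="133.09" y2="162.95"/>
<line x1="211.36" y1="212.00" x2="211.36" y2="210.13"/>
<line x1="213.44" y1="212.00" x2="213.44" y2="170.88"/>
<line x1="239.35" y1="212.00" x2="239.35" y2="201.84"/>
<line x1="295.29" y1="212.00" x2="295.29" y2="196.42"/>
<line x1="302.25" y1="212.00" x2="302.25" y2="191.60"/>
<line x1="324.17" y1="212.00" x2="324.17" y2="171.16"/>
<line x1="330.58" y1="212.00" x2="330.58" y2="199.86"/>
<line x1="338.55" y1="212.00" x2="338.55" y2="52.56"/>
<line x1="381.36" y1="212.00" x2="381.36" y2="190.17"/>
<line x1="419.84" y1="212.00" x2="419.84" y2="48.19"/>
<line x1="428.90" y1="212.00" x2="428.90" y2="204.67"/>
<line x1="430.00" y1="212.00" x2="430.00" y2="172.28"/>
</g>
</g>
<g class="signal-labels" fill="#333333" font-family="sans-serif" font-size="11" text-anchor="middle">
<text x="419.84" y="51.00">461.66</text>
<text x="338.55" y="51.00">381.46</text>
<text x="133.09" y="158.95">178.76</text>
<text x="213.44" y="166.88">258.03</text>
<text x="324.17" y="167.16">367.28</text>
</g>
<g class="legend" font-family="sans-serif" font-size="11">
<rect x="333.20" y="48.00" width="88.80" height="27.00" fill="#ffffff" stroke="#333333" fill-opacity="0.8"/>
<g class="legend-entry">
<line x1="341.20" y1="61.50" x2="355.20" y2="61.50" stroke="#1f77b4" stroke-width="2"/>
<text x="361.20" y="65.35" fill="#333333">series-1</text>
</g>
</g>
<g class="axes" stroke="#333333" stroke-width="1" font-family="sans-serif" font-size="11" fill="none">
<line x1="64.00" y1="212.00" x2="430.00" y2="212.00"/>
<line x1="64.00" y1="40.00" x2="64.00" y2="212.00"/>
<line x1="154.62" y1="212.00" x2="154.62" y2="217.00"/>
<text x="154.62" y="228.00" fill="#333333" stroke="none" text-anchor="middle">200</text>
<line x1="255.98" y1="212.00" x2="255.98" y2="217.00"/>
<text x="255.98" y="228.00" fill="#333333" stroke="none" text-anchor="middle">300</text>
<line x1="357.34" y1="212.00" x2="357.34" y2="217.00"/>
<text x="357.34" y="228.00" fill="#333333" stroke="none" text-anchor="middle">400</text>
<line x1="59.00" y1="48.19" x2="64.00" y2="48.19"/>
<text x="56.00" y="52.04" fill="#333333" stroke="none" text-anchor="end">100</text>
<line x1="59.00" y1="130.10" x2="64.00" y2="130.10"/>
<text x="56.00" y="133.95" fill="#333333" stroke="none" text-anchor="end">50</text>
<line x1="59.00" y1="212.00" x2="64.00" y2="212.00"/>
<text x="56.00" y="215.85" fill="#333333" stroke="none" text-anchor="end">0</text>
<text x="247.00" y="252.00" fill="#333333" stroke="none" text-anchor="middle">m/z</text>
<text x="14.00" y="126.00" fill="#333333" stroke="none" text-anchor="middle" transform="rotate(-90 14.00 126.00)">Intensity</text>
<text x="247.00" y="28.00" fill="#333333" stroke="none" text-anchor="middle" font-size="14" font-weight="bold">Mass spectrum</text>
</g>
</svg>
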