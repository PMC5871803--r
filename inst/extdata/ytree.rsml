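<?xml version="1.0" encoding="UTF-8"?>
<rsml version="1.0">
  <metadata>
    <version>1</version>
    <unit>cm</unit>
    <resolution>1</resolution>
  </metadata>
  <scene>
    <plant ID="plant_1">
      <root ID="axis">
        <geometry>
          <polyline>
            <point x="0" y="0"/>
            <point x="0" y="2"/>
            <point x="0" y="5"/>
          </polyline>
        </geometry>
        <functions>
          <function name="diameter" domain="polyline">
            <sample value="0.12"/>
            <sample value="0.11"/>
            <sample value="0.10"/>
          </function>
        </functions>
        <root ID="lat1">
          <geometry>
            <polyline>
              <point x="0" y="2"/>
              <point x="1" y="2.5"/>
            </polyline>
          </geometry>
          <functions>
            <function name="diameter" domain="polyline">
              <sample value="0.06"/>
              <sample value="0.05"/>
            </function>
          </functions>
        </root>
        <root ID="lat2">
          <geometry>
            <polyline>
              <point x="0" y="5"/>
              <point x="-1" y="5.5"/>
              <point x="-1.5" y="6"/>
            </polyline>
          </geometry>
          <functions>
            <function name="diameter" domain="polyline">
              <sample value="0.05"/>
              <sample value="0.05"/>
              <sample value="0.04"/>
            </function>
          </functions>
        </root>
      </root>
    </plant>
  </scene>
</rsml>
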