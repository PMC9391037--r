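session_id,pregnancy_id,gestational_day,kind,onset_s,offset_s,partial
P1_E093,P1,93,orofacial,83.4333333333333,84.0333333333333,0
P1_E093,P1,93,orofacial,174.866666666667,175.066666666667,0
P1_E093,P1,93,orofacial,175.333333333333,175.833333333333,0
P1_E093,P1,93,orofacial,176.166666666667,176.5,0
P1_E093,P1,93,orofacial,176.733333333333,177.3,0
P1_E093,P1,93,orofacial,177.466666666667,178.066666666667,0
P1_E093,P1,93,orofacial,178.233333333333,178.8,0
P1_E093,P1,93,orofacial,179,179.733333333333,0
P1_E093,P1,93,orofacial,210.3,210.533333333333,0
P1_E093,P1,93,orofacial,253.533333333333,254.1,1
P1_E093,P1,93,orofacial,284.133333333333,284.833333333333,0
P1_E093,P1,93,orofacial,360.366666666667,360.533333333333,0
P1_E093,P1,93,orofacial,360.733333333333,360.9,0
P1_E093,P1,93,orofacial,361.066666666667,361.533333333333,0
P1_E093,P1,93,orofacial,361.8,362.066666666667,0
P1_E093,P1,93,orofacial,362.3,362.6,0
P1_E093,P1,93,orofacial,362.766666666667,363.033333333333,0
P1_E093,P1,93,orofacial,363.2,363.666666666667,0
P1_E093,P1,93,orofacial,363.933333333333,364.133333333333,0
P1_E093,P1,93,orofacial,517.733333333333,518.2,0
P1_E093,P1,93,orofacial,518.6,519.066666666667,0
P1_E093,P1,93,orofacial,519.4,519.8,0
P1_E093,P1,93,orofacial,520.266666666667,520.9,0
P1_E093,P1,93,orofacial,594.133333333333,594.533333333333,0
P1_E093,P1,93,orofacial,594.9,595.233333333333,0
P1_E093,P1,93,orofacial,664.466666666667,665.3,0
P1_E093,P1,93,orofacial,680.933333333333,681.333333333333,0
P1_E093,P1,93,orofacial,681.566666666667,682,0
P1_E093,P1,93,orofacial,682.4,683,0
P1_E093,P1,93,orofacial,843.2,843.766666666667,0
P1_E093,P1,93,orofacial,844.133333333333,844.633333333333,0
P1_E093,P1,93,head,27.3666666666667,28.1666666666667,0
P1_E093,P1,93,head,71.5666666666667,72.6,0
P1_E093,P1,93,head,81.9333333333333,83.6333333333333,0
P1_E093,P1,93,head,171.366666666667,172.133333333333,0
P1_E093,P1,93,head,173.533333333333,176.333333333333,0
P1_E093,P1,93,head,208.333333333333,208.966666666667,0
P1_E093,P1,93,head,210.366666666667,211.233333333333,0
P1_E093,P1,93,head,231.666666666667,232.866666666667,0
P1_E093,P1,93,head,249.266666666667,250.166666666667,0
P1_E093,P1,93,head,254.033333333333,255.466666666667,0
P1_E093,P1,93,head,283.366666666667,284.533333333333,0
P1_E093,P1,93,head,361.966666666667,363.166666666667,0
P1_E093,P1,93,head,465.533333333333,467.466666666667,0
P1_E093,P1,93,head,474.333333333333,477.5,0
P1_E093,P1,93,head,494.066666666667,494.6,0
P1_E093,P1,93,head,517.266666666667,519.333333333333,0
P1_E093,P1,93,head,527.833333333333,530,0
P1_E093,P1,93,head,533.733333333333,534.733333333333,0
P1_E093,P1,93,head,593.8,595.433333333333,0
P1_E093,P1,93,head,664.233333333333,666.433333333333,0
P1_E093,P1,93,head,679.5,681.066666666667,0
P1_E093,P1,93,head,681.933333333333,683.7,0
P1_E093,P1,93,head,805.6,806.166666666667,0
P1_E093,P1,93,head,813.066666666667,814.133333333333,0
P1_E093,P1,93,head,838.233333333333,839.066666666667,0
P1_E093,P1,93,head,844.066666666667,844.833333333333,0
P1_E093,P1,93,head,870,871,0
P1_E146,P1,146,orofacial,26.5666666666667,27.1333333333333,0
P1_E146,P1,146,orofacial,95.7666666666667,96.6666666666667,0
P1_E146,P1,146,orofacial,126.866666666667,127.433333333333,0
P1_E146,P1,146,orofacial,127.666666666667,128.233333333333,0
P1_E146,P1,146,orofacial,128.466666666667,128.7,0
P1_E146,P1,146,orofacial,128.933333333333,129.333333333333,0
P1_E146,P1,146,orofacial,129.5,129.966666666667,0
P1_E146,P1,146,orofacial,130.133333333333,130.466666666667,0
P1_E146,P1,146,orofacial,130.7,131.066666666667,0
P1_E146,P1,146,orofacial,131.266666666667,131.833333333333,0
P1_E146,P1,146,orofacial,132.066666666667,132.4,0
P1_E146,P1,146,orofacial,233.633333333333,234.633333333333,0
P1_E146,P1,146,orofacial,234.8,235.533333333333,0
P1_E146,P1,146,orofacial,235.7,236.533333333333,0
P1_E146,P1,146,orofacial,236.833333333333,237.4,0
P1_E146,P1,146,orofacial,237.733333333333,238.566666666667,0
P1_E146,P1,146,orofacial,238.7,239.433333333333,0
P1_E146,P1,146,orofacial,308,308.6,0
P1_E146,P1,146,orofacial,308.9,309.366666666667,0
P1_E146,P1,146,orofacial,309.7,310.066666666667,0
P1_E146,P1,146,orofacial,310.2,310.433333333333,0
P1_E146,P1,146,orofacial,310.633333333333,310.933333333333,0
P1_E146,P1,146,orofacial,311.2,311.733333333333,0
P1_E146,P1,146,orofacial,311.9,312.3,0
P1_E146,P1,146,orofacial,312.533333333333,313.1,0
P1_E146,P1,146,orofacial,326.666666666667,326.966666666667,0
P1_E146,P1,146,orofacial,327.166666666667,327.7,0
P1_E146,P1,146,orofacial,345.366666666667,345.7,0
P1_E146,P1,146,orofacial,346.033333333333,346.6,0
P1_E146,P1,146,orofacial,346.866666666667,347.2,0
P1_E146,P1,146,orofacial,347.366666666667,347.666666666667,0
P1_E146,P1,146,orofacial,347.9,348.166666666667,0
P1_E146,P1,146,orofacial,348.333333333333,348.833333333333,0
P1_E146,P1,146,orofacial,348.966666666667,349.366666666667,0
P1_E146,P1,146,orofacial,349.7,350.1,0
P1_E146,P1,146,orofacial,383.866666666667,384.366666666667,0
P1_E146,P1,146,orofacial,384.7,385.066666666667,0
P1_E146,P1,146,orofacial,385.2,385.833333333333,0
P1_E146,P1,146,orofacial,386,386.3,0
P1_E146,P1,146,orofacial,386.633333333333,387,0
P1_E146,P1,146,orofacial,387.133333333333,387.466666666667,0
P1_E146,P1,146,orofacial,387.733333333333,387.933333333333,0
P1_E146,P1,146,orofacial,388.1,388.666666666667,0
P1_E146,P1,146,orofacial,507.366666666667,507.5,1
P1_E146,P1,146,orofacial,507.666666666667,507.866666666667,1
P1_E146,P1,146,orofacial,508.1,508.333333333333,1
P1_E146,P1,146,orofacial,508.633333333333,508.866666666667,1
P1_E146,P1,146,orofacial,509.2,509.433333333333,1
P1_E146,P1,146,orofacial,509.733333333333,509.966666666667,1
P1_E146,P1,146,orofacial,510.133333333333,510.3,1
P1_E146,P1,146,orofacial,510.533333333333,510.766666666667,1
P1_E146,P1,146,orofacial,510.933333333333,511.066666666667,1
P1_E146,P1,146,orofacial,582.333333333333,583,0
P1_E146,P1,146,orofacial,723.066666666667,723.8,0
P1_E146,P1,146,orofacial,800.3,801.066666666667,0
P1_E146,P1,146,orofacial,813.133333333333,813.666666666667,1
P1_E146,P1,146,orofacial,813.833333333333,814.5,1
P1_E146,P1,146,orofacial,814.966666666667,815.433333333333,1
P1_E146,P1,146,head,120.066666666667,121.3,0
P1_E146,P1,146,head,123.566666666667,124.733333333333,0
P1_E146,P1,146,head,452.7,453.666666666667,0
P1_E146,P1,146,head,470.9,472.566666666667,0
P1_E146,P1,146,head,655.9,657.2,0
P1_E146,P1,146,head,878.733333333333,882.1,0
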